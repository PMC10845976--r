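# map from bipartition (the side not holding the outgroup, as a sorted
# tip-label key) to numeric support, built on the tree BEFORE rooting;
# rooting preserves bipartitions but ape shuffles node labels
bipartition_support_map <- function(tree, outgroup_id) {
  if (is.null(tree$node.label)) return(list())
  ntip <- length(tree$tip.label)
  sets <- phangorn::Descendants(tree, (ntip + 1L):(ntip + tree$Nnode),
                                type = "tips")
  out <- list()
  for (k in seq_along(sets)) {
    s <- suppressWarnings(as.numeric(tree$node.label[k]))
    if (is.na(s)) next
    side <- tree$tip.label[sets[[k]]]
    if (outgroup_id %in% side) side <- setdiff(tree$tip.label, side)
    out[[paste(sort(side), collapse = "\r")]] <- s
  }
  out
}

#' Assign reference-anchored clades on a rooted survey tree
#'
#' The tree is rooted on the outgroup. For each reference leaf, its clade is
#' the largest rooted subtree containing that reference, no other reference
#' and not the outgroup. Leaves not claimed by any reference clade are
#' partitioned into maximal reference-free rooted subtrees whose parent edge
#' has bootstrap support at least `support_threshold` (subtrees without a
#' stored support value pass); these new clades are numbered `Velvet1`,
#' `Velvet2`, ... in decreasing member count, ties broken by first member id.
#'
#' @param tree A `phylo` tree whose tips include the references and the
#'   outgroup; `node.label` may hold bootstrap supports.
#' @param references Named character vector mapping reference tip ids to
#'   anchor names (e.g. `c(ref_vea = "VeA", ...)`).
#' @param outgroup_id Tip id used to root the tree.
#' @param support_threshold Minimum percent support for cutting a new
#'   (VelvetN) clade; default 50.
#' @return A tibble with columns `anchor`, `anchor_id` (`NA` for VelvetN
#'   clades), `member_ids` (list column, excluding reference and outgroup
#'   tips), `n_members` and `singleton` (reference clades containing only the
#'   reference itself are flagged).
#' @export
assign_clades <- function(tree, references, outgroup_id,
                          support_threshold = 50) {
  stopifnot(inherits(tree, "phylo"))
  ref_ids <- names(references)
  if (is.null(ref_ids) || anyDuplicated(ref_ids))
    stop("references must be a named vector with unique tip ids", call. = FALSE)
  missing_tips <- setdiff(c(ref_ids, outgroup_id), tree$tip.label)
  if (length(missing_tips) > 0L)
    stop(sprintf("tips absent from tree: %s",
                 paste(missing_tips, collapse = ", ")), call. = FALSE)
  if (outgroup_id %in% ref_ids)
    stop("degenerate resolution: the outgroup cannot also be a reference",
         call. = FALSE)
  support_map <- bipartition_support_map(tree, outgroup_id)
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE,
                      edgelabel = TRUE)
  ntip <- length(rooted$tip.label)
  tipsets <- phangorn::Descendants(rooted, (ntip + 1L):(ntip + rooted$Nnode),
                                   type = "tips")
  tips_of <- function(node) {
    if (node <= ntip) node else tipsets[[node - ntip]]
  }
  ref_tip <- match(ref_ids, rooted$tip.label)
  out_tip <- match(outgroup_id, rooted$tip.label)

  out <- list()
  claimed <- integer(0)
  for (k in seq_along(ref_ids)) {
    leaf <- ref_tip[k]
    best <- leaf
    for (a in phangorn::Ancestors(rooted, leaf, type = "all")) {
      tips <- tips_of(a)
      if (out_tip %in% tips) break
      if (any(setdiff(ref_tip, leaf) %in% tips)) break
      best <- a
    }
    tips <- tips_of(best)
    members <- setdiff(rooted$tip.label[tips], c(ref_ids, outgroup_id))
    out[[length(out) + 1L]] <- tibble::tibble(
      anchor = unname(references[k]), anchor_id = ref_ids[k],
      member_ids = list(members), n_members = length(members),
      singleton = length(members) == 0L
    )
    claimed <- union(claimed, tips)
  }

  remaining <- setdiff(seq_len(ntip), union(claimed, c(ref_tip, out_tip)))
  velvet_sets <- list()
  root_node <- ntip + 1L
  support_of <- function(tips) {
    key <- paste(sort(rooted$tip.label[tips]), collapse = "\r")
    s <- support_map[[key]]
    if (is.null(s)) Inf else s
  }
  visit <- function(node) {
    tips <- tips_of(node)
    if (length(remaining) > 0L && all(tips %in% remaining)) {
      if (node <= ntip || support_of(tips) >= support_threshold) {
        velvet_sets[[length(velvet_sets) + 1L]] <<- tips
        return(invisible(NULL))
      }
    }
    if (node > ntip) {
      for (ch in phangorn::Children(rooted, node)) visit(ch)
    }
    invisible(NULL)
  }
  visit(root_node)
  if (length(velvet_sets) > 0L) {
    member_lists <- lapply(velvet_sets, function(t) sort(rooted$tip.label[t]))
    ord <- order(-lengths(member_lists),
                 vapply(member_lists, `[[`, "", 1L))
    member_lists <- member_lists[ord]
    for (k in seq_along(member_lists)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        anchor = sprintf("Velvet%d", k), anchor_id = NA_character_,
        member_ids = list(member_lists[[k]]),
        n_members = length(member_lists[[k]]), singleton = FALSE
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Compose a clade name from its taxonomic groups and anchor
#'
#' Each group contributes its first three letters (first letter capitalized);
#' abbreviations are hyphen-joined in the input order and followed by the
#' anchor name, e.g. `("Pezizomycotina", "VosA")` gives `"Pez-VosA"` and
#' `("Saccharomycotina", "Taphrinomycotina")` with `"VelB"` gives
#' `"Sac-Tap-VelB"`.
#'
#' @param groups Character vector of taxonomic group names (ordered).
#' @param anchor Anchor name (`"VeA"`, `"VelB"`, `"VelC"`, `"VosA"` or
#'   `"VelvetN"`).
#' @return The clade name string.
#' @export
name_clade <- function(groups, anchor) {
  stopifnot(length(groups) >= 1L)
  abbr <- paste0(toupper(substr(groups, 1L, 1L)),
                 tolower(substr(groups, 2L, 3L)))
  paste(c(abbr, anchor), collapse = "-")
}

#' Attach group-aware clade names to clade assignments
#'
#' @param assignments Output of [assign_clades()].
#' @param group_of Named character vector mapping protein ids to taxonomic
#'   groups.
#' @return `assignments` with added `groups_spanned` (list column, groups in
#'   alphabetical order) and `clade_name`.
#' @export
name_clades <- function(assignments, group_of) {
  gs <- lapply(assignments$member_ids, function(ids) {
    sort(unique(unname(group_of[ids])))
  })
  nm <- vapply(seq_len(nrow(assignments)), function(k) {
    if (length(gs[[k]]) == 0L) return(assignments$anchor[k])
    name_clade(gs[[k]], assignments$anchor[k])
  }, "")
  dplyr::mutate(assignments, groups_spanned = gs, clade_name = nm)
}

#' Two-clan partition of a clade-consensus tree
#'
#' Midpoint-roots the consensus tree; the two child subtrees of the root are
#' the clans, labelled by which anchor leaf each contains. It is an error for
#' both anchors to fall in one subtree — no silent guess is made.
#'
#' @param tree A `phylo` tree of clade-consensus leaves.
#' @param velb_anchor,vosa_anchor Leaf labels anchoring the two clans.
#' @return A named list of two character vectors of leaf labels
#'   (`VelB`, `VosA`).
#' @export
clan_partition <- function(tree, velb_anchor, vosa_anchor) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(c(velb_anchor, vosa_anchor) %in% tree$tip.label))
    stop("both anchors must be leaves of the tree", call. = FALSE)
  mid <- phangorn::midpoint(tree)
  ntip <- length(mid$tip.label)
  root_node <- ntip + 1L
  kids <- phangorn::Children(mid, root_node)
  if (length(kids) != 2L)
    stop("midpoint root is not binary; clan partition undefined", call. = FALSE)
  sets <- lapply(kids, function(ch) {
    t <- if (ch <= ntip) ch else
      phangorn::Descendants(mid, ch, type = "tips")[[1]]
    mid$tip.label[t]
  })
  in_velb <- vapply(sets, function(s) velb_anchor %in% s, TRUE)
  in_vosa <- vapply(sets, function(s) vosa_anchor %in% s, TRUE)
  if (which(in_velb) == which(in_vosa))
    stop("clan partition error: both anchors fall in the same subtree of the midpoint root",
         call. = FALSE)
  list(VelB = sets[[which(in_velb)]], VosA = sets[[which(in_vosa)]])
}
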