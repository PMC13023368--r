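# Dollo parsimony loss mapping: a character gained once at the root and
# lost any number of times. On a rooted (binary or deterministically
# resolved) tree, the unique minimal loss set is one loss on the stem edge
# of every maximal clade whose informative tips are all absent; unknown
# tips are uninformative for clade maximality.

# normalize a tree input to a rooted phylo with resolved polytomies
.as_rooted_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                     error = function(e) NULL)
    if (is.null(tree) || length(tree$tip.label) == 0L) {
      stop("invalid newick tree", call. = FALSE)
    }
  }
  stopifnot(inherits(tree, "phylo"))
  if (tree$Nnode != length(tree$tip.label) - 1L) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tree
}

# node labels for reporting: tip labels for tips, node.label or node<k>
.node_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- character(length(node))
  tipq <- node <= n_tip
  out[tipq] <- tree$tip.label[node[tipq]]
  if (any(!tipq)) {
    ni <- node[!tipq]
    lab <- if (!is.null(tree$node.label)) tree$node.label[ni - n_tip]
           else rep(NA_character_, length(ni))
    bad <- is.na(lab) | !nzchar(lab)
    lab[bad] <- paste0("node", ni[bad])
    out[!tipq] <- lab
  }
  out
}

#' Map character losses on a tree under Dollo parsimony
#'
#' Given per-tip presence of one character ("present"/"absent"/"unknown",
#' or a logical vector with NA = unknown), returns the minimal set of
#' edges on which a loss must be placed so that, with a single gain at the
#' root, every absent tip lies below a loss and no present tip does: one
#' loss on the stem edge of each maximal absent-only clade. Unknown tips
#' are uninformative. If every informative tip is absent, the single loss
#' sits on the root edge (reported with `parent = NA`).
#'
#' @param tree `ape::phylo` or newick string; polytomies are resolved
#'   deterministically.
#' @param presence named vector over the tips.
#' @return a tibble of loss events: `parent`, `child` (labels), `branch`
#'   (`"parent->child"`), `tips_affected` (comma-joined absent tips below
#'   the edge), `n_tips_affected`; zero rows when nothing was lost.
#' @examples
#' dollo_losses("((A,B),(C,D));",
#'              c(A = "present", B = "present", C = "absent", D = "absent"))
#' @export
dollo_losses <- function(tree, presence) {
  tree <- .as_rooted_tree(tree)
  tips <- tree$tip.label
  pres <- presence[tips]
  if (anyNA(names(pres)) || length(pres) != length(tips)) {
    stop("presence must be named with every tree tip", call. = FALSE)
  }
  if (is.logical(pres)) {
    pres <- ifelse(is.na(pres), "unknown", ifelse(pres, "present", "absent"))
  }
  stopifnot(all(pres %in% c("present", "absent", "unknown")))
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  # per-node informative tip counts, post-order
  n_pres <- integer(n_node); n_abs <- integer(n_node)
  n_pres[seq_len(n_tip)] <- pres == "present"
  n_abs[seq_len(n_tip)] <- pres == "absent"
  po <- if (identical(attr(tree, "order"), "postorder")) tree
        else ape::reorder.phylo(tree, "postorder")
  tips_below <- c(as.list(seq_len(n_tip)),
                  rep(list(integer(0)), tree$Nnode))
  for (k in seq_len(nrow(po$edge))) {
    e <- po$edge[k, ]
    n_pres[e[1]] <- n_pres[e[1]] + n_pres[e[2]]
    n_abs[e[1]] <- n_abs[e[1]] + n_abs[e[2]]
    tips_below[[e[1]]] <- c(tips_below[[e[1]]], tips_below[[e[2]]])
  }
  absent_only <- n_abs > 0L & n_pres == 0L
  empty <- tibble::tibble(parent = character(), child = character(),
                          branch = character(), tips_affected = character(),
                          n_tips_affected = integer())
  if (n_abs[root] == 0L) return(empty)
  # absent tips below each node (postorder tip lists, no clade extraction)
  desc_absent <- function(node) {
    below <- tips[sort(tips_below[[node]])]
    below[pres[below] == "absent"]
  }
  if (absent_only[root]) {
    aff <- desc_absent(root)
    return(tibble::tibble(parent = NA_character_,
                          child = .node_label(tree, root),
                          branch = paste0("root->", .node_label(tree, root)),
                          tips_affected = paste(aff, collapse = ","),
                          n_tips_affected = length(aff)))
  }
  # loss edges: absent-only child whose parent is not absent-only
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  loss <- which(absent_only[child] & !absent_only[parent])
  pl <- .node_label(tree, parent[loss])
  cl <- .node_label(tree, child[loss])
  aff <- vapply(loss, function(k) {
    paste(desc_absent(child[k]), collapse = ",")
  }, character(1))
  n_aff <- n_abs[child[loss]]
  o <- order(cl)
  tibble::new_tibble(list(parent = pl[o], child = cl[o],
                          branch = paste0(pl[o], "->", cl[o]),
                          tips_affected = aff[o],
                          n_tips_affected = as.integer(n_aff[o])),
                     nrow = length(o))
}

#' Combine per-species trait presence into telomerase status calls
#'
#' @param presence tibble with columns `species`, `telomere_motif`, `tr`,
#'   `tert`, each "present"/"absent"/"unknown".
#' @return the input with a `status` column: concurrent absence of all
#'   three -> "putative telomerase loss"; all present ->
#'   "telomerase-positive"; present/absent conflict -> "inconclusive
#'   (conflicting evidence)"; otherwise unknowns -> "inconclusive
#'   (missing data)".
#' @export
classify_status <- function(presence) {
  chars <- c("telomere_motif", "tr", "tert")
  stopifnot(all(chars %in% names(presence)))
  presence$status <- vapply(seq_len(nrow(presence)), function(i) {
    v <- unlist(presence[i, chars], use.names = FALSE)
    if (all(v == "absent")) "putative telomerase loss"
    else if (all(v == "present")) "telomerase-positive"
    else if (any(v == "present") && any(v == "absent"))
      "inconclusive (conflicting evidence)"
    else "inconclusive (missing data)"
  }, character(1))
  presence
}

#' Dollo loss events for all three telomerase characters
#'
#' @param presence tibble as in [classify_status()].
#' @param tree `ape::phylo` or newick string covering `presence$species`.
#' @return tibble of loss events with a `character` column.
#' @export
map_telomerase_losses <- function(presence, tree) {
  chars <- c("telomere_motif", "tr", "tert")
  dplyr::bind_rows(lapply(chars, function(ch) {
    v <- setNames(presence[[ch]], presence$species)
    ev <- dollo_losses(tree, v)
    if (nrow(ev) > 0L) ev$character <- ch
    ev
  }))
}
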