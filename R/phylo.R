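## Synonymous-distance phylogenetics: ts/tv-weighted (modified Nei-Gojobori)
## synonymous p-distances with gamma correction, Saitou-Nei neighbor joining
## with the Studier-Keppler criterion, codon-resampling bootstrap, and
## Newick output. Trees are returned as ape-compatible "phylo" objects.

## per-pair per-codon synonymous difference and weighted site arrays
syn_pair_arrays <- function(pd, R = 2) {
  tabs <- ng_diff_tables()
  sW <- ng_site_table("weighted", R)
  n <- pd$n
  k <- ncol(pd$codon_idx)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  Sd <- matrix(0, np, max(k, 1))
  sbar <- matrix(0, np, max(k, 1))
  if (k > 0) {
    for (z in seq_len(np)) {
      ia <- pd$codon_idx[pairs[1, z], ]
      ib <- pd$codon_idx[pairs[2, z], ]
      Sd[z, ] <- tabs$Sd[cbind(ia, ib)]
      sbar[z, ] <- (sW[ia] + sW[ib]) / 2
    }
  }
  list(pairs = pairs, Sd = Sd, sbar = sbar, n = n, k = k, ids = pd$ids)
}

syn_dist_from_arrays <- function(arr, codon_subset = NULL, gamma_a = 1) {
  sel <- if (is.null(codon_subset)) seq_len(arr$k) else codon_subset
  D <- matrix(0, arr$n, arr$n, dimnames = list(arr$ids, arr$ids))
  for (z in seq_len(ncol(arr$pairs))) {
    p <- sum(arr$Sd[z, sel]) / sum(arr$sbar[z, sel])
    d <- suppressWarnings(gamma_correct(p, gamma_a))
    i <- arr$pairs[1, z]; j <- arr$pairs[2, z]
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Pairwise synonymous distance matrix
#'
#' For each pair, the synonymous p-distance is the summed Nei-Gojobori
#' synonymous differences divided by the transition/transversion-weighted
#' ("modified", bias `R`) potential synonymous site count, gamma-corrected
#' with shape `gamma_a` (shape 1 gives `d = p/(1 - 4p/3)`). Saturated pairs
#' (`p >= 0.75`) are flagged `NA`.
#'
#' @inheritParams pi_by_class
#' @param R transition/transversion weight for potential site counts
#' @param gamma_a gamma shape parameter for rate variation across sites
#' @return symmetric matrix with taxon labels; class `syn_dist_matrix`
#' @export
syn_distance_matrix <- function(aln, mask, ids = NULL, R = 2, gamma_a = 1) {
  pd <- popgen_data(aln, mask, ids)
  if (ncol(pd$codon_idx) == 0) stop("no usable codons for synonymous distances")
  arr <- syn_pair_arrays(pd, R)
  D <- syn_dist_from_arrays(arr, gamma_a = gamma_a)
  class(D) <- c("syn_dist_matrix", class(D))
  D
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Ties in Q
#' are broken deterministically in favour of the lowest-index pair. Negative
#' branch lengths are clamped to zero; the total clamped deficit is recorded
#' in the `"clamped"` attribute. The tree is unrooted.
#'
#' @param D symmetric distance matrix with labels (e.g. from
#'   [syn_distance_matrix()])
#' @return an object of class `phylo` (ape-compatible)
#' @export
nj_tree <- function(D) {
  D <- unclass(D)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("undefined distances for pairs: ",
         paste(apply(bad, 1, function(ij)
           paste(labels[ij], collapse = "-")), collapse = ", "))
  }
  clamped <- 0
  clamp <- function(x) {
    clamped <<- clamped + sum(pmax(-x, 0))
    pmax(x, 0)
  }
  ## clusters carry newick fragments; placeholder labels survive the Newick
  ## round trip and are replaced by the originals afterwards
  ph <- sprintf("t%d", seq_len(n))
  frag <- as.list(ph)
  act <- seq_len(n)
  Dm <- D
  while (length(act) > 3) {
    m <- length(act)
    Da <- Dm[act, act]
    r <- rowSums(Da)
    Q <- (m - 2) * Da - outer(r, r, "+")
    diag(Q) <- Inf
    ## lowest-index pair among Q minima (column-major scan of upper pairs)
    qmin <- min(Q)
    hit <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    d_ij <- Da[i, j]
    li <- clamp(d_ij / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(d_ij - li)
    ai <- act[i]; aj <- act[j]
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[[ai]], li, frag[[aj]], lj)
    ## distances from the new node
    newd <- (Dm[ai, act] + Dm[aj, act] - d_ij) / 2
    Dm <- rbind(cbind(Dm, 0), 0)
    newid <- nrow(Dm)
    Dm[newid, act] <- newd
    Dm[act, newid] <- newd
    Dm[newid, newid] <- 0
    frag[[newid]] <- newfrag
    act <- c(setdiff(act, c(ai, aj)), newid)
  }
  ## final three-cluster join (star): lengths from the three-point equations
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- clamp((Dm[a, b] + Dm[a, c3] - Dm[b, c3]) / 2)
  lb <- clamp((Dm[a, b] + Dm[b, c3] - Dm[a, c3]) / 2)
  lc <- clamp((Dm[a, c3] + Dm[b, c3] - Dm[a, b]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[[a]], la, frag[[b]], lb, frag[[c3]], lc)
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[match(tree$tip.label, ph)]
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for the synonymous-distance NJ tree
#'
#' Resamples codon columns with replacement (`B` replicates), recomputes the
#' synonymous distance matrix and NJ tree for each replicate, and reports for
#' every internal edge of the original tree the percentage of replicates
#' containing the same bipartition. Replicates with saturated distances are
#' skipped and counted in the `"skipped"` attribute; supports are percentages
#' of the successful replicates.
#'
#' @inheritParams syn_distance_matrix
#' @param B number of bootstrap replicates
#' @param seed integer seed (resampling is fully reproducible)
#' @return the original NJ `phylo` tree with `node.label` set to integer
#'   supports (root label empty)
#' @export
bootstrap_support <- function(aln, mask, ids = NULL, B = 1000, seed = 1,
                              R = 2, gamma_a = 1) {
  pd <- popgen_data(aln, mask, ids)
  if (ncol(pd$codon_idx) == 0) stop("no usable codons for synonymous distances")
  arr <- syn_pair_arrays(pd, R)
  D0 <- syn_dist_from_arrays(arr, gamma_a = gamma_a)
  tree <- nj_tree(D0)
  k <- arr$k
  boots <- list()
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      sel <- sample.int(k, k, replace = TRUE)
      Db <- syn_dist_from_arrays(arr, sel, gamma_a)
      if (anyNA(Db)) { skipped <- skipped + 1L; next }
      boots[[length(boots) + 1L]] <- nj_tree(Db)
    }
  })
  if (length(boots) == 0) stop("all bootstrap replicates saturated")
  cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  supp <- round(100 * cnt / length(boots))
  ## the basal trifurcation of an unrooted tree is not a bipartition
  tree$node.label <- as.character(supp)
  tree$node.label[1] <- ""
  attr(tree, "skipped") <- skipped
  attr(tree, "n_replicates") <- length(boots)
  tree
}

## newick escaping: quote labels containing spaces or newick metacharacters
quote_label <- function(x) {
  ifelse(grepl("[][ \t():;,']", x),
         paste0("'", gsub("'", "''", x), "'"), x)
}

#' Write a tree in Newick format
#'
#' Branch lengths are always written; internal node labels (e.g. bootstrap
#' supports) are written when present. Labels containing spaces or Newick
#' metacharacters are single-quoted.
#'
#' @param tree an object of class `phylo`
#' @param file optional path; when `NULL` the Newick string is returned
#' @return the Newick string, invisibly when written to a file
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node, edge_idx) {
    len <- if (is.null(edge_idx)) NULL else tree$edge.length[edge_idx]
    body <- if (node <= n) {
      quote_label(tree$tip.label[node])
    } else {
      ch <- kids[[as.character(node)]]
      inner <- paste(vapply(ch, function(e)
        rec(tree$edge[e, 2], e), ""), collapse = ",")
      lab <- if (!is.null(tree$node.label)) {
        quote_label(tree$node.label[node - n])
      } else ""
      paste0("(", inner, ")", lab)
    }
    if (is.null(len)) body else sprintf("%s:%.10g", body, len)
  }
  nwk <- paste0(rec(root, NULL), ";")
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}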