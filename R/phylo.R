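#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via `ape::nj`) with deterministic
#' handling of the occasional negative branch length: the negative edge is
#' clamped to zero and its deficit moved to the sibling edge, the standard
#' practice for distance trees.
#'
#' @param d A symmetric non-negative distance matrix (zero diagonal) or
#'   `dist` object over >= 3 labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("`d` must be square")
  if (nrow(d) < 3L) abort("need at least three labels")
  if (any(d < 0)) abort("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-12)) abort("`d` must be symmetric")
  if (any(diag(d) != 0)) abort("`d` must have a zero diagonal")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tree)
}

clamp_negative_edges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sib <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sib)) {
      tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap supports by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds the
#' neighbor-joining tree on the p-distance matrix of each replicate, and
#' reports for each internal split of the original tree the percentage of
#' replicates containing it. Zero-length internal edges are collapsed before
#' split counting (an all-identical alignment therefore yields no resolved,
#' supportable edges). Reproducible for a fixed seed and invariant to taxon
#' order up to the seed-to-column mapping.
#'
#' @param sequences Named character vector of *aligned*, equal-length
#'   sequences (gaps `-` allowed; gapped columns are excluded pairwise).
#' @param n_replicates Bootstrap replicates.
#' @param seed Integer seed.
#' @return The collapsed original tree (`ape::phylo`) with `node.label` set
#'   to integer bootstrap percentages (`""` for the root).
#' @export
bootstrap_supports <- function(sequences, n_replicates = 1000L, seed = 1L) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) abort("sequences must be aligned to equal length")
  if (length(sequences) < 4L) abort("need at least four sequences for supports")
  m <- do.call(rbind, strsplit(sequences, ""))
  rownames(m) <- names(sequences) %||% paste0("seq", seq_len(nrow(m)))
  ref <- ape::di2multi(nj_tree(char_matrix_pdist(m)), tol = 1e-10)
  if (ref$Nnode <= 1L) {
    ref$node.label <- rep("", ref$Nnode)
    return(ref)
  }
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      ape::di2multi(nj_tree(char_matrix_pdist(m[, cols, drop = FALSE])),
                    tol = 1e-10)
    })
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / n_replicates)
  supports[1L] <- NA # root pseudo-node carries no split
  ref$node.label <- ifelse(is.na(supports), "", as.character(supports))
  ref
}

# pairwise-deletion p-distance matrix from a character matrix (rows = taxa)
char_matrix_pdist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      d[i, j] <- d[j, i] <- if (any(ok)) {
        sum(m[i, ok] != m[j, ok]) / sum(ok)
      } else 0
    }
  }
  d
}

#' Write (and read back) a tree as newick
#'
#' Standard newick with branch lengths; any bootstrap percentages stored in
#' `node.label` appear as internal node labels. Labels containing
#' newick-reserved characters are single-quoted.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  has_reserved <- function(x) grepl("[](),:;'\"[[:space:]]|\\[", x)
  # labels with reserved characters are swapped for placeholders before the
  # serialiser (which would otherwise mangle them) and re-injected quoted
  subst <- character(0)
  mask <- function(labels) {
    bad <- which(has_reserved(labels))
    for (i in bad) {
      ph <- sprintf("xAMPQx%dx", length(subst) + 1L)
      subst[[ph]] <<- sprintf("'%s'", gsub("'", "''", labels[i]))
      labels[i] <- ph
    }
    labels
  }
  tree$tip.label <- mask(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- mask(tree$node.label)
  txt <- ape::write.tree(tree)
  for (ph in names(subst)) txt <- gsub(ph, subst[[ph]], txt, fixed = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
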