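#' Median-center each feature row
#'
#' Subtracts from every feature (protein) row the median of its observed
#' values, the standard preparation before expression clustering. Missing
#' cells are untouched; idempotent.
#'
#' @param m Log2 matrix (features x samples) with \code{NA} for missing.
#' @return The row-centered matrix.
#' @export
median_center_features <- function(m) {
  m <- as.matrix(m)
  for (i in seq_len(nrow(m))) {
    obs <- m[i, ][!is.na(m[i, ])]
    if (length(obs) == 0L)
      stop("feature '", rownames(m)[i], "' has no observed values")
    m[i, ] <- m[i, ] - stats::median(obs)
  }
  m
}

#' Euclidean distance with missing-value rescaling
#'
#' Pairwise Euclidean distances over the chosen axis. For two vectors with
#' missing entries the squared distance over the jointly observed positions
#' is rescaled by \code{K / |O|} (full length over number of shared
#' positions), the convention used by the Cluster 3.0 tool, so that
#' incomplete pairs remain comparable with complete ones:
#' \code{d = sqrt((K/|O|) * sum_{i in O} (u_i - v_i)^2)}.
#'
#' @param m Numeric matrix (features x samples).
#' @param axis \code{"features"} (rows, default) or \code{"samples"}
#'   (columns).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
euclidean_distance <- function(m, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  x <- if (axis == "samples") t(as.matrix(m)) else as.matrix(m)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 items to compute distances")
  K <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    shared <- !is.na(x[i, ]) & !is.na(x[j, ])
    n_sh <- sum(shared)
    if (n_sh == 0L)
      stop("no shared observations between '", rownames(x)[i], "' and '",
           rownames(x)[j], "'")
    d[i, j] <- d[j, i] <-
      sqrt((K / n_sh) * sum((x[i, shared] - x[j, shared])^2))
  }
  d
}

#' Agglomerative complete-linkage clustering
#'
#' Classic bottom-up merging: at every step the pair of clusters with the
#' smallest complete-linkage distance (maximum pairwise member distance) is
#' joined. Ties are broken deterministically by the smallest older node
#' index, then the smallest younger one (leaves are numbered 1..n in input
#' order; internal nodes n+1, n+2, ... in merge order). The leaf ordering
#' follows the convention that the left subtree is the one containing the
#' lowest original index.
#'
#' @param d Symmetric distance matrix.
#' @return An object of class \code{LinkageTree}: \code{merges} (data frame
#'   node_a, node_b, height, new_node_id), \code{order} (leaf permutation),
#'   \code{labels}, \code{n}.
#' @export
complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2L, isTRUE(all.equal(d, t(d))))
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)            # node ids of active clusters
  dist_act <- d                   # distances between active clusters
  members <- as.list(seq_len(n))  # leaves per node id (grows)
  merges <- data.frame(node_a = integer(n - 1L), node_b = integer(n - 1L),
                       height = numeric(n - 1L),
                       new_node_id = integer(n - 1L))
  children <- vector("list", 2L * n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    # find minimum with deterministic tie-break on (older id, younger id)
    best <- NULL
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      ids <- sort(c(active[i], active[j]))
      cand <- c(dist_act[i, j], ids)
      if (is.null(best) || cand[1] < best[1] ||
          (cand[1] == best[1] &&
           (cand[2] < best[2] || (cand[2] == best[2] && cand[3] < best[3])))) {
        best <- cand
        bi <- i; bj <- j
      }
    }
    new_id <- n + step
    merges$node_a[step] <- min(active[bi], active[bj])
    merges$node_b[step] <- max(active[bi], active[bj])
    merges$height[step] <- best[1]
    merges$new_node_id[step] <- new_id
    children[[new_id]] <- c(merges$node_a[step], merges$node_b[step])
    members[[new_id]] <- c(members[[active[bi]]], members[[active[bj]]])
    # complete linkage: distance to merged cluster = max of the two
    newd <- pmax(dist_act[bi, ], dist_act[bj, ])[-c(bi, bj)]
    keep <- setdiff(seq_len(k), c(bi, bj))
    dist_act <- dist_act[keep, keep, drop = FALSE]
    dist_act <- rbind(cbind(dist_act, newd), c(newd, 0))
    active <- c(active[keep], new_id)
  }
  # leaf order: left subtree = subtree containing the lower original index
  order_of <- function(id) {
    if (id <= n) return(id)
    ch <- children[[id]]
    mins <- vapply(ch, function(c2) min(members[[c2]]), 0)
    ch <- ch[order(mins)]
    c(order_of(ch[1]), order_of(ch[2]))
  }
  structure(list(merges = merges, order = order_of(2L * n - 1L),
                 labels = labels, n = n),
            class = "LinkageTree")
}

#' Convert a LinkageTree to an hclust object
#' @param x A \code{LinkageTree}.
#' @param ... Unused.
#' @return A \code{stats::hclust} object (for plotting / cutting).
#' @export
as.hclust.LinkageTree <- function(x, ...) {
  n <- x$n
  enc <- function(id) if (id <= n) -id else id - n
  merge <- cbind(vapply(x$merges$node_a, enc, 0L),
                 vapply(x$merges$node_b, enc, 0L))
  structure(list(merge = merge, height = x$merges$height, order = x$order,
                 labels = x$labels, method = "complete",
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a LinkageTree into k clusters
#' @param tree A \code{LinkageTree}.
#' @param k Number of clusters.
#' @return Integer cluster assignment named by leaf label.
#' @export
cut_tree <- function(tree, k = 2L) {
  stats::cutree(as.hclust.LinkageTree(tree), k = k)
}

#' Bidirectional hierarchical clustering of an expression matrix
#'
#' Row-centers the matrix by feature medians, clusters both proteins (rows)
#' and samples (columns) by complete linkage on missing-rescaled Euclidean
#' distances, and reorders the matrix to the two leaf orders. The 2-cut
#' purity of the sample tree -- the average fraction of samples in each
#' cluster belonging to that cluster's majority experimental group -- is
#' reported as a separation score.
#'
#' @param m Log2 abundance matrix (proteins x samples), typically restricted
#'   to a differentially-expressed protein list.
#' @param design Optional \code{StudyDesign} used for the purity score.
#' @param center Median-center rows first (default TRUE).
#' @return List with \code{protein_tree}, \code{sample_tree} (the protein
#'   tree is \code{NULL} for a single protein), \code{matrix} (reordered,
#'   centered), and \code{purity} (\code{NA} without a design).
#' @export
cluster_bidirectional <- function(m, design = NULL, center = TRUE) {
  m <- as.matrix(m)
  if (center) m <- median_center_features(m)
  sample_tree <- complete_linkage(euclidean_distance(m, axis = "samples"))
  protein_tree <- if (nrow(m) >= 2L)
    complete_linkage(euclidean_distance(m, axis = "features")) else NULL
  row_ord <- if (is.null(protein_tree)) 1L else protein_tree$order
  reordered <- m[row_ord, sample_tree$order, drop = FALSE]
  purity <- NA_real_
  if (!is.null(design)) {
    cl <- cut_tree(sample_tree, 2L)
    grp <- design$group_label[match(names(cl), design$sample_id)]
    purity <- mean(vapply(split(grp, cl), function(g)
      max(table(g)) / length(g), 0))
  }
  list(protein_tree = protein_tree, sample_tree = sample_tree,
       matrix = reordered, purity = purity)
}

#' Write clustering results in Cluster 3.0 format
#'
#' Writes the reordered matrix as a \code{.cdt} file plus \code{.gtr}
#' (protein tree) and \code{.atr} (sample tree) files loadable in TreeView,
#' and a plain merge-list TSV per tree.
#'
#' @param clust Result of [cluster_bidirectional()].
#' @param basename Output path prefix (files get .cdt/.gtr/.atr suffixes).
#' @return Invisibly, the paths written.
#' @export
write_cluster3 <- function(clust, basename) {
  m <- clust$matrix
  paths <- character(0)
  gene_ids <- paste0("GENE", seq_len(nrow(m)), "X")
  node_names <- function(tree) paste0("NODE", seq_len(tree$n - 1L), "X")
  tree_file <- function(tree, ids, path) {
    nm <- node_names(tree)
    ref <- function(id) if (id <= tree$n) ids[id] else nm[id - tree$n]
    maxh <- max(tree$merges$height)
    corr <- if (maxh > 0) 1 - tree$merges$height / maxh else
      rep(1, nrow(tree$merges))
    lines <- sprintf("%s\t%s\t%s\t%s", nm,
                     vapply(tree$merges$node_a, ref, ""),
                     vapply(tree$merges$node_b, ref, ""),
                     .fmt_num(corr))
    writeLines(lines, path)
    path
  }
  if (!is.null(clust$protein_tree)) {
    ord_ids <- gene_ids  # already in reordered (leaf) order
    orig_ids <- gene_ids[order(clust$protein_tree$order)]
    paths <- c(paths, tree_file(clust$protein_tree,
                                orig_ids, paste0(basename, ".gtr")))
  }
  arr_ids <- paste0("ARRY", seq_len(ncol(m)), "X")
  orig_arr <- arr_ids[order(clust$sample_tree$order)]
  paths <- c(paths, tree_file(clust$sample_tree, orig_arr,
                              paste0(basename, ".atr")))
  # CDT: reordered matrix with GID/AID rows as Cluster 3.0 writes them
  cdt <- paste0(basename, ".cdt")
  con <- file(cdt, "wb")
  header <- c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(paste(c("AID", "", "", "", arr_ids), collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", "", "", "",
                     rep("1", ncol(m))), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    vals <- ifelse(is.na(m[i, ]), "", .fmt_num(m[i, ]))
    writeLines(paste(c(gene_ids[i], rownames(m)[i], rownames(m)[i], "1",
                       vals), collapse = "\t"), con)
  }
  close(con)
  paths <- c(paths, cdt)
  for (nm2 in c("protein_tree", "sample_tree")) {
    tree <- clust[[nm2]]
    if (is.null(tree)) next
    mpath <- paste0(basename, ".", nm2, ".tsv")
    write_results_table(tree$merges, mpath)
    paths <- c(paths, mpath)
  }
  invisible(paths)
}
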