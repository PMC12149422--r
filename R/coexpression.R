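#' Pick a soft threshold for a scale-free coexpression network
#'
#' For each candidate power, the unsigned adjacency `|cor(g_i, g_j)|^beta` is
#' formed, connectivities `k_i` are binned (~10 bins) and the scale-free fit
#' R^2 is the squared correlation of `log10(freq)` vs `log10(mean k)` over the
#' non-empty bins. The smallest beta reaching `rsq_cut` is selected; if none
#' does, the beta with maximal R^2 is used.
#'
#' @param expr genes x samples numeric matrix (no zero-variance genes).
#' @param powers candidate betas (default 1:20).
#' @param rsq_cut scale-free fit target (default 0.8).
#' @param n_bins connectivity histogram bins.
#' @return list with `beta`, `rsq_by_power` (named numeric) and `cor_mat`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, rsq_cut = 0.8, n_bins = 10L) {
  if (ncol(expr) < 30)
    warning("fewer than 30 samples; soft-threshold fit may be unstable")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) stop("zero-variance gene(s); filter before network construction")
  cm <- abs(stats::cor(t(expr)))
  diag(cm) <- 0
  rsq <- stats::setNames(rep(NA_real_, length(powers)), powers)
  for (i in seq_along(powers)) {
    k <- rowSums(cm^powers[i])
    if (max(k) <= 0 || stats::sd(k) == 0) next
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- tabulate(bin, n_bins)
    mk <- vapply(seq_len(n_bins), function(b)
      if (freq[b] > 0) mean(k[as.integer(bin) == b]) else NA_real_, numeric(1))
    ok <- freq > 0 & mk > 0
    if (sum(ok) < 3) next
    rsq[i] <- stats::cor(log10(freq[ok]), log10(mk[ok]))^2
  }
  beta <- if (any(!is.na(rsq) & rsq >= rsq_cut))
    powers[which(!is.na(rsq) & rsq >= rsq_cut)[1]]
  else if (any(!is.na(rsq))) powers[which.max(rsq)]
  else powers[1]
  list(beta = beta, rsq_by_power = rsq, cor_mat = cm)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with unit
#' diagonal; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency symmetric matrix, zero diagonal, entries in `[0, 1]`.
#' @return TOM similarity matrix (symmetric, unit diagonal).
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-10)))
    stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  (tom + t(tom)) / 2
}

#' Detect coexpression modules by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage clustering on `1 - TOM`; the tree is cut at the height (on
#' a scanned grid) that maximizes the number of clusters meeting
#' `min_module_size` (ties toward the lower height). Clusters below the
#' minimum size become "grey"; surviving modules are named by standard color
#' aliases in descending size order.
#'
#' @param tom TOM similarity from [tom_matrix()].
#' @param min_module_size minimum genes per module (default 100).
#' @param max_heights cap on the number of scanned cut heights (the scan uses
#'   the midpoints between consecutive merge heights, subsampled above this).
#' @return list with `modules` (named character vector gene -> color label),
#'   `cut_height`, `tree` (hclust).
#' @export
detect_modules <- function(tom, min_module_size = 100L, max_heights = 2000L) {
  diss <- 1 - tom
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  # candidate cuts: midpoints between consecutive merge heights (every distinct
  # partition of the dendrogram), subsampled if very many
  hh <- sort(unique(tree$height))
  hs <- if (length(hh) > 1) (hh[-1] + hh[-length(hh)]) / 2 else hh
  if (length(hs) > max_heights)
    hs <- hs[unique(round(seq(1, length(hs), length.out = max_heights)))]
  best_h <- NA; best_n <- -1L
  for (h in hs) {
    cl <- stats::cutree(tree, h = h)
    nbig <- sum(table(cl) >= min_module_size)
    if (nbig > best_n) { best_n <- nbig; best_h <- h }
  }
  cl <- stats::cutree(tree, h = best_h)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  if (length(big) == 0) {
    warning("no cluster reaches min_module_size; all genes grey")
    modules <- rep("grey", length(cl))
  } else {
    palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                 "black", "pink", "magenta", "purple", "greenyellow", "tan")
    big <- big[order(sizes[big], decreasing = TRUE)]
    alias <- stats::setNames(rep("grey", length(sizes)), names(sizes))
    alias[big] <- c(palette, paste0("module", seq_len(max(0, length(big) - length(palette)))))[
      seq_along(big)]
    modules <- alias[as.character(cl)]
  }
  names(modules) <- rownames(tom) %||% names(cl)
  list(modules = modules, cut_height = best_h, tree = tree)
}

#' Module eigengenes
#'
#' First principal component of each module's standardized expression,
#' unit-norm, sign-oriented so that the mean correlation with the module's
#' member genes is positive.
#'
#' @param expr genes x samples matrix.
#' @param modules gene -> module label vector ("grey" excluded).
#' @return samples x modules matrix of eigengene scores.
#' @export
module_eigengenes <- function(expr, modules) {
  mods <- setdiff(unique(modules), "grey")
  eg <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), mods))
  for (m in mods) {
    sub <- expr[names(modules)[modules == m], , drop = FALSE]
    zs <- t(scale(t(sub)))
    pc <- stats::prcomp(t(zs), center = FALSE, scale. = FALSE)
    v <- pc$x[, 1]
    v <- v / sqrt(sum(v^2))
    if (mean(stats::cor(v, t(sub))) < 0) v <- -v
    eg[, m] <- v
  }
  eg
}

#' Module-trait correlations and selection of the most significant module
#'
#' Pearson correlation of each module eigengene with each trait, with p-values
#' from the t distribution (df n-2). The selected module minimizes p against
#' the primary (first) trait; ties break toward larger `|r|`.
#'
#' @param expr genes x samples matrix.
#' @param modules gene -> module label vector.
#' @param traits data.frame/matrix of per-sample traits (first column = the
#'   radscore or primary trait); rows aligned with `colnames(expr)`.
#' @return object of class `module_assignment`: list with `modules`,
#'   `eigengenes`, `module_trait` (long data.frame), `selected_module`.
#' @export
module_trait <- function(expr, modules, traits) {
  traits <- as.data.frame(traits)
  if (nrow(traits) != ncol(expr))
    stop("traits rows must align with expression samples")
  eg <- module_eigengenes(expr, modules)
  if (ncol(eg) == 0)
    stop("no non-grey modules; cannot compute module-trait correlations")
  n <- nrow(eg)
  rows <- list()
  for (m in colnames(eg)) for (tr in names(traits)) {
    r <- stats::cor(eg[, m], traits[[tr]])
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    rows[[length(rows) + 1]] <- data.frame(module = m, trait = tr, r = r, p = p)
  }
  mt <- do.call(rbind, rows)
  primary <- mt[mt$trait == names(traits)[1], ]
  primary <- primary[order(primary$p, -abs(primary$r)), ]
  structure(list(modules = modules, eigengenes = eg, module_trait = mt,
                 selected_module = primary$module[1]),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- table(x$modules)
  cat("Coexpression modules:",
      paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "), "\n")
  sel <- x$module_trait[x$module_trait$module == x$selected_module &
                          x$module_trait$trait == x$module_trait$trait[1], ]
  cat("Selected module:", x$selected_module,
      sprintf("(r = %.3f, p = %.2e vs primary trait)\n", sel$r[1], sel$p[1]))
  invisible(x)
}

#' Hub genes of a module
#'
#' With an interaction edge list: the two genes of highest degree in the
#' module-induced subgraph. Without one: the two genes of highest intramodular
#' connectivity (row sums of the module's adjacency). Ties break
#' lexicographically.
#'
#' @param module_genes character vector of the module's gene IDs.
#' @param edges optional data.frame with two gene columns (an interaction
#'   edge list); ignored with a warning if it touches no module gene.
#' @param adjacency optional full adjacency matrix (fallback ranking).
#' @param n_hubs how many hub genes (default 2).
#' @return character vector of hub gene IDs.
#' @export
hub_genes <- function(module_genes, edges = NULL, adjacency = NULL, n_hubs = 2L) {
  if (length(module_genes) == 0) stop("empty module")
  if (!is.null(edges)) {
    e <- edges[edges[[1]] %in% module_genes & edges[[2]] %in% module_genes, , drop = FALSE]
    if (nrow(e) > 0) {
      g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                         vertices = sort(module_genes))
      deg <- igraph::degree(g)
      ord <- order(-deg, names(deg))
      return(names(deg)[ord][seq_len(min(n_hubs, length(deg)))])
    }
    warning("edge list touches no module gene; falling back to adjacency ranking")
  }
  if (is.null(adjacency)) stop("no edge list match and no adjacency fallback")
  sub <- adjacency[module_genes, module_genes, drop = FALSE]
  k <- rowSums(sub)
  ord <- order(-k, names(k))
  names(k)[ord][seq_len(min(n_hubs, length(k)))]
}

#' Hypergeometric over-representation of annotation terms
#'
#' One-sided upper-tail hypergeometric p per term with Benjamini-Hochberg
#' correction; the report keeps the five smallest p-values below `p_cut`.
#'
#' @param module_genes genes of the selected module.
#' @param annotation data.frame with columns `term_id`, `term_name`, `gene`.
#' @param universe all gene IDs (must contain the module genes).
#' @param p_cut display threshold (default 0.05).
#' @return list with `table` (term_id, term_name, term_size, overlap,
#'   expected, p, fdr, ordered by p) and `top` (<= 5 rows with p < p_cut).
#' @export
hypergeom_enrichment <- function(module_genes, annotation, universe,
                                 p_cut = 0.05) {
  if (nrow(annotation) == 0) stop("empty annotation table")
  if (!all(module_genes %in% universe))
    stop("universe must contain all module genes")
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  m <- length(unique(module_genes))
  terms <- unique(annotation[c("term_id", "term_name")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    gs <- unique(annotation$gene[annotation$term_id == terms$term_id[i]])
    K <- length(gs)
    q <- length(intersect(gs, module_genes))
    p <- stats::phyper(q - 1, K, N - K, m, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               term_size = K, overlap = q, expected = m * K / N, p = p)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p), ]
  rownames(tab) <- NULL
  list(table = tab, top = utils::head(tab[tab$p < p_cut, ], 5))
}

#' Run the full coexpression analysis
#'
#' Soft threshold, adjacency, TOM, module detection, module-trait correlation
#' and hub-gene ranking in one call.
#'
#' @param expr genes x samples matrix.
#' @param traits per-sample trait data.frame (first column primary).
#' @param min_module_size minimum module size (default 100).
#' @param powers candidate soft-threshold powers.
#' @param edges optional interaction edge list for hub ranking.
#' @return `module_assignment` with extra fields `beta`, `rsq_by_power`,
#'   `hubs`.
#' @export
coexpression_analysis <- function(expr, traits, min_module_size = 100L,
                                  powers = 1:20, edges = NULL) {
  st <- pick_soft_threshold(expr, powers)
  adj <- st$cor_mat^st$beta
  diag(adj) <- 0
  tom <- tom_matrix(adj)
  rownames(tom) <- colnames(tom) <- rownames(expr)
  det <- detect_modules(tom, min_module_size)
  ma <- module_trait(expr, det$modules, traits)
  sel_genes <- names(det$modules)[det$modules == ma$selected_module]
  ma$beta <- st$beta
  ma$rsq_by_power <- st$rsq_by_power
  ma$cut_height <- det$cut_height
  ma$hubs <- hub_genes(sel_genes, edges = edges, adjacency = adj)
  ma
}
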