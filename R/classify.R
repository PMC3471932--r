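# Distances, hierarchical clustering, MDS and group I-V assignment.

#' Pearson distance between two response vectors
#'
#' `1 - r`, with `r` the Pearson correlation of the components: 0 for
#' identical profiles, 1 for uncorrelated, 2 for perfectly anti-correlated.
#' A (near-)constant vector has no defined correlation; by convention the
#' distance is set to 1 with a warning (flat, group-IV-like vectors are
#' the expected offenders).
#'
#' @param u,v numeric vectors of equal length >= 3.
#' @param var_tol variance below which a vector counts as constant.
#' @return distance in \[0, 2\].
#' @export
pearson_distance <- function(u, v, var_tol = 1e-6) {
  if (length(u) != length(v)) stop_contract("vectors differ in length")
  if (length(u) < 3) stop_contract("Pearson distance needs length >= 3")
  if (stats::var(u) < var_tol || stats::var(v) < var_tol) {
    warn("near-constant vector: Pearson distance undefined, set to 1")
    return(1)
  }
  1 - cor(u, v)
}

#' Pairwise distance matrix of SCRIT vectors
#'
#' @param scrit a `scrit_tbl` (>= 2 vectors).
#' @param metric `"pearson"` (secondary screen) or `"euclidean"` (primary
#'   screen).
#' @param var_tol variance threshold for the constant-vector convention.
#' @return a `dist` object with attributes `metric` and `Labels` =
#'   `"compound:replicate"`.
#' @export
scrit_dist <- function(scrit, metric = c("pearson", "euclidean"),
                       var_tol = 1e-6) {
  metric <- match.arg(metric)
  m <- scrit_matrix(scrit)
  if (nrow(m) < 2) stop_contract("need >= 2 vectors for a distance matrix")
  if (metric == "euclidean") {
    d <- dist(m, method = "euclidean")
  } else {
    flat <- apply(m, 1, stats::var) < var_tol
    if (any(flat)) {
      warn(sprintf("%d near-constant vector(s): Pearson distances set to 1",
                   sum(flat)))
    }
    dm <- 1 - suppressWarnings(cor(t(m)))
    dm[flat, ] <- 1
    dm[, flat] <- 1
    diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  attr(d, "metric") <- metric
  d
}

#' Agglomerative clustering of a distance matrix
#'
#' Thin wrapper around [stats::hclust()] with average linkage by default
#' (the linkage is configurable; merge heights are checked to be
#' non-decreasing).
#'
#' @param d a `dist`, e.g. from [scrit_dist()].
#' @param linkage one of `"average"`, `"single"`, `"complete"`,
#'   `"ward.D2"`.
#' @return an `hclust` object (attribute `metric` copied from `d`).
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  linkage <- match.arg(linkage, c("average", "single", "complete", "ward.D2"))
  hc <- hclust(d, method = linkage)
  stopifnot(!is.unsorted(hc$height))
  attr(hc, "metric") <- attr(d, "metric")
  hc
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Eigendecomposition-based (Torgerson) MDS: deterministic, no random
#' initialization. Coordinates are centered; each axis is reflected so
#' that its largest-magnitude coordinate is positive, fixing the sign
#' convention for reproducibility. If fewer positive eigenvalues than
#' `dims` exist, the embedding is reduced with a warning.
#'
#' @param d a `dist`.
#' @param dims 2 or 3.
#' @return tibble with `item` and `mds1..mds<dims>`; eigenvalues in the
#'   `"eig"` attribute.
#' @export
mds_embed <- function(d, dims = 2) {
  if (!dims %in% 2:3 && dims != 1) stop_contract("`dims` must be 1, 2 or 3")
  n_items <- attr(d, "Size")
  if (dims > n_items - 1) {
    warn(sprintf("%d item(s) support at most %d dimension(s); embedding reduced",
                 n_items, n_items - 1))
    dims <- n_items - 1
  }
  fit <- cmdscale(d, k = dims, eig = TRUE)
  pts <- fit$points
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (ncol(pts) < dims || n_pos < dims) {
    k <- min(ncol(pts), max(n_pos, 1))
    warn(sprintf("only %d positive eigenvalue(s); embedding reduced to %d-D",
                 n_pos, k))
    pts <- pts[, seq_len(k), drop = FALSE]
  }
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  out <- as_tibble(setNames(as.data.frame(pts),
                            paste0("mds", seq_len(ncol(pts)))))
  out <- mutate(out, item = labels(d) %||% rownames(pts), .before = 1)
  attr(out, "eig") <- fit$eig
  out
}

#' Label flat clusters with mechanistic groups
#'
#' Cuts the dendrogram into `k` flat clusters, finds each cluster's medoid
#' (minimum summed within-cluster distance, first index on ties), and
#' labels the cluster with the nearest reference fingerprint by Pearson
#' distance. Clusters whose medoid is farther than `ceiling_distance` from
#' every reference are labeled `"other"` for manual review.
#'
#' @param hc an `hclust` from [hierarchical_cluster()].
#' @param scrit the clustered `scrit_tbl` (same row order as the distance
#'   matrix).
#' @param references named list of reference vectors (one per group,
#'   e.g. from [expected_scrit()]), or `NULL` for the built-in archetype
#'   references matched to the SCRIT's parameters/doses/conditions.
#' @param k number of flat clusters.
#' @param ceiling_distance Pearson distance beyond which a cluster is
#'   `"other"`.
#' @param d the distance matrix used for clustering (for medoids);
#'   recomputed when omitted.
#' @return tibble: `item`, `compound`, `replicate`, `cluster`, `group`;
#'   compound-level majority labels in attribute `"compound_groups"`.
#' @export
assign_groups <- function(hc, scrit, references = NULL, k = 5,
                          ceiling_distance = 0.8, d = NULL) {
  references <- references %||% archetype_references(scrit)
  if (length(references) == 0) stop_contract("no reference fingerprints")
  d <- d %||% scrit_dist(scrit, metric = "pearson")
  dm <- as.matrix(d)
  cl <- cutree(hc, k = k)
  m <- scrit_matrix(scrit)
  cluster_ids <- sort(unique(cl))
  cluster_group <- vapply(cluster_ids, function(cc) {
    idx <- which(cl == cc)
    med <- idx[which.min(rowSums(dm[idx, idx, drop = FALSE]))]
    dd <- vapply(references, function(ref) {
      suppressWarnings(pearson_distance(m[med, ], ref))
    }, numeric(1))
    if (min(dd) > ceiling_distance) "other" else names(dd)[which.min(dd)]
  }, character(1))
  names(cluster_group) <- as.character(cluster_ids)
  out <- tibble(
    item = rownames(m),
    compound = scrit$compound,
    replicate = scrit$replicate,
    cluster = unname(cl),
    group = unname(cluster_group[as.character(cl)])
  )
  majority <- out %>%
    group_by(.data$compound) %>%
    summarise(group = names(sort(table(.data$group), decreasing = TRUE))[1],
              .groups = "drop")
  attr(out, "compound_groups") <- majority
  out
}

# Built-in reference fingerprints: analytic expected SCRITs of the five
# archetype groups (plus the inverse-TMRM phenotype), matched to the
# SCRIT's own parameters, doses and conditions.
archetype_references <- function(scrit) {
  grp_of <- c(I_direct_mito = "I", II_glu_independent = "II",
              III_glu_dependent = "III", IV_inactive = "IV",
              V_uncoupler = "V", inverse_tmrm = "other")
  refs <- lapply(setNames(nm = ARCHETYPES), function(a) {
    expected_scrit(make_phenotype_model(a),
                   parameters = attr(scrit, "parameters"),
                   doses = attr(scrit, "doses"),
                   conditions = attr(scrit, "conditions"))
  })
  names(refs) <- unname(grp_of[names(refs)])
  refs
}

#' End-to-end classification of SCRIT vectors
#'
#' Distance matrix, average-linkage dendrogram, classical MDS and group
#' labels in one object.
#'
#' @param scrit a `scrit_tbl`.
#' @param metric distance metric (see [scrit_dist()]).
#' @param linkage see [hierarchical_cluster()].
#' @param k flat clusters for labeling.
#' @param references see [assign_groups()].
#' @param dims MDS dimensionality.
#' @return object of class `scrit_classification`: list with `dist`, `hc`,
#'   `mds`, `groups`, `scrit`, `config`, `config_hash`.
#' @export
classify_scrit <- function(scrit, metric = "pearson", linkage = "average",
                           k = 5, references = NULL, dims = 2) {
  d <- scrit_dist(scrit, metric = metric)
  hc <- hierarchical_cluster(d, linkage = linkage)
  mds <- mds_embed(d, dims = dims)
  groups <- assign_groups(hc, scrit, references = references, k = k, d = d)
  cfg <- list(metric = metric, linkage = linkage, k = k, dims = dims)
  structure(list(dist = d, hc = hc, mds = mds, groups = groups,
                 scrit = scrit, config = cfg,
                 config_hash = config_hash(cfg)),
            class = "scrit_classification")
}

#' @export
print.scrit_classification <- function(x, ...) {
  cat(sprintf("<scrit_classification> %d vectors, %s distance, %s linkage, k = %d\n",
              nrow(x$groups), x$config$metric, x$config$linkage, x$config$k))
  print(table(x$groups$group))
  invisible(x)
}

#' Write a classification bundle to a directory
#'
#' Distance matrix (TSV), dendrogram (Newick), MDS coordinates (TSV) and
#' group labels (TSV), plus a JSON provenance record with the
#' configuration hash.
#'
#' @param x a `scrit_classification`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_classification <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- as.matrix(x$dist)
  readr::write_tsv(
    mutate(as_tibble(dm), item = rownames(dm), .before = 1),
    file.path(dir, "distance_matrix.tsv"), progress = FALSE)
  writeLines(hclust_newick(x$hc), file.path(dir, "dendrogram.nwk"))
  readr::write_tsv(x$mds, file.path(dir, "mds.tsv"), progress = FALSE)
  readr::write_tsv(x$groups, file.path(dir, "groups.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(config = x$config, config_hash = x$config_hash),
    file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(dir)
}

# Serialize an hclust as a Newick string (branch lengths from merge heights).
hclust_newick <- function(hc) {
  lab <- gsub("[,();:]", "_", hc$labels)
  build <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.6g", lab[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.6g",
              build(hc$merge[i, 1], h), build(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- length(hc$height)
  paste0("(", build(hc$merge[n, 1], hc$height[n]), ",",
         build(hc$merge[n, 2], hc$height[n]), ");")
}
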