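#' Expression set container
#'
#' Bundles a log2 expression matrix (features in rows, samples in columns)
#' with a sample-to-group annotation table. Values are log2-scale intensities
#' as produced by RMA-style preprocessing; the package never re-normalizes.
#'
#' @param values Numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids). All values must be finite.
#' @param groups Data frame with columns `sample_id` and `group` covering
#'   every sample exactly once.
#' @return An object of class `expression_set`: a list with elements
#'   `values` (the matrix) and `groups` (a tibble).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' g <- data.frame(sample_id = c("s1", "s2"), group = c("ctl", "dis"))
#' expression_set(m, g)
#' @export
expression_set <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    abort("`values` must have rownames (features) and colnames (samples).")
  }
  check_unique(fid, "feature id")
  check_unique(sid, "sample id")
  if (!all(is.finite(values))) {
    abort("expression values must all be finite.")
  }
  groups <- as_tibble(as.data.frame(groups))
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("`groups` needs columns `sample_id` and `group`.")
  }
  groups <- groups[, c("sample_id", "group")]
  groups$sample_id <- as.character(groups$sample_id)
  groups$group <- as.character(groups$group)
  check_unique(groups$sample_id, "sample id in groups table")
  missing <- setdiff(sid, groups$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples without a group label: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  groups <- groups[match(sid, groups$sample_id), ]
  structure(list(values = values, groups = groups), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$values), " features x ", ncol(x$values),
      " samples\n", sep = "")
  tab <- table(x$groups$group)
  cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn expression_set sample ids of an expression set belonging to
#'   one group.
#' @param x An `expression_set`.
#' @param group Group label.
#' @export
samples_in_group <- function(x, group) {
  stopifnot(inherits(x, "expression_set"))
  x$groups$sample_id[x$groups$group == group]
}

#' Long-format view of an expression set
#'
#' @param x An `expression_set`.
#' @param ... Unused.
#' @return Tibble with columns `feature_id`, `sample_id`, `group`, `value`.
#' @export
as_tibble.expression_set <- function(x, ...) {
  tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  ) |>
    left_join(x$groups, by = "sample_id") |>
    select("feature_id", "sample_id", "group", "value")
}

#' Drug-perturbation rank database
#'
#' A CMAP-style rank database: one column per perturbation instance, holding
#' a full permutation rank of all probes. Rank 1 is the probe most
#' up-regulated by the treatment; rank n the most down-regulated. The
#' permutation property is verified for every instance at construction.
#'
#' @param ranks Integer matrix, probes x instances, rownames = probe ids,
#'   colnames = instance ids; every column a permutation of `1:nrow(ranks)`.
#' @param meta Data frame with columns `instance_id`, `perturbagen`, `dose`,
#'   `cell`, one row per instance (order is aligned to `ranks` columns).
#' @return Object of class `rank_db` with elements `ranks` and `meta`.
#' @export
rank_db <- function(ranks, meta) {
  if (!is.matrix(ranks)) abort("`ranks` must be a matrix (probes x instances).")
  storage.mode(ranks) <- "integer"
  pid <- rownames(ranks)
  iid <- colnames(ranks)
  if (is.null(pid) || is.null(iid)) {
    abort("`ranks` must have probe rownames and instance colnames.")
  }
  check_unique(pid, "probe id")
  check_unique(iid, "instance id")
  n <- nrow(ranks)
  for (j in seq_len(ncol(ranks))) {
    check_permutation(ranks[, j], n, iid[j])
  }
  meta <- as_tibble(as.data.frame(meta))
  need <- c("instance_id", "perturbagen", "dose", "cell")
  if (!all(need %in% names(meta))) {
    abort(paste0("`meta` needs columns: ", paste(need, collapse = ", ")))
  }
  meta$instance_id <- as.character(meta$instance_id)
  check_unique(meta$instance_id, "instance id in meta")
  if (!setequal(meta$instance_id, iid)) {
    abort("meta instance ids and rank matrix columns disagree.")
  }
  meta <- meta[match(iid, meta$instance_id), need]
  structure(list(ranks = ranks, meta = meta), class = "rank_db")
}

#' @export
print.rank_db <- function(x, ...) {
  cat("<rank_db> ", nrow(x$ranks), " probes x ", ncol(x$ranks),
      " instances (", length(unique(x$meta$perturbagen)),
      " perturbagens)\n", sep = "")
  invisible(x)
}

#' Up/down query signature
#'
#' A pair of disjoint feature sets describing a transcriptional state, used
#' to query a rank database: `up` features rise in the condition of interest,
#' `down` features fall. Lives either in probe space or gene-symbol space.
#'
#' @param up,down Character vectors of feature ids; internally deduplicated,
#'   must be disjoint.
#' @param space `"probe"` or `"gene"`.
#' @return Object of class `signature_set`.
#' @examples
#' signature_set(c("p1", "p2"), "p3", space = "probe")
#' @export
signature_set <- function(up, down, space = c("probe", "gene")) {
  space <- match.arg(space)
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both) > 0) {
    abort(paste0("up and down sets overlap: ",
                 paste(head(both, 5), collapse = ", ")))
  }
  structure(list(up = up, down = down, space = space),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> [", x$space, " space] ", length(x$up), " up / ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

# internal validators shared by containers and readers ------------------------

check_unique <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d) > 0) {
    abort(paste0("duplicate ", what, ": ", paste(head(d, 5), collapse = ", ")))
  }
  invisible(ids)
}

check_permutation <- function(r, n, label) {
  if (anyNA(r) || length(r) != n || !setequal(r, seq_len(n))) {
    abort(paste0("instance '", label, "': ranks are not a permutation of 1..",
                 n, "."))
  }
  invisible(r)
}
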