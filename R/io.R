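#' Read and write expression matrices
#'
#' The canonical on-disk form is TSV: a header row of sample ids, the first
#' column holding feature ids, the remainder log2 expression values. Sample
#' groups live in a separate two-column TSV (`sample_id`, `group`).
#' Gzip-compressed files (`.gz`) are read and written transparently.
#'
#' @param path Expression TSV (features x samples).
#' @param groups_path Two-column TSV mapping sample id to group label.
#' @return `read_expression()` returns an [expression_set()].
#' @examples
#' d <- tempfile(); g <- tempfile()
#' writeLines(c("feature_id\ts1\ts2", "a\t1\t2", "b\t3\t4"), d)
#' writeLines(c("sample_id\tgroup", "s1\tctl", "s2\tdis"), g)
#' read_expression(d, g)
#' @export
read_expression <- function(path, groups_path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2) abort("expression TSV needs a feature column plus samples.")
  sid <- names(df)[-1]
  check_unique(sid, paste0("sample id in '", basename(path), "'"))
  fid <- as.character(df[[1]])
  check_unique(fid, paste0("feature id in '", basename(path), "'"))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("expression values must be numeric.")
  dimnames(m) <- list(fid, sid)
  g <- read_tsv_strict(groups_path)
  if (ncol(g) < 2) abort("groups TSV needs two columns: sample id, group.")
  groups <- tibble(sample_id = as.character(g[[1]]), group = as.character(g[[2]]))
  expression_set(m, groups)
}

#' @rdname read_expression
#' @param x An `expression_set`.
#' @export
write_expression <- function(x, path, groups_path) {
  stopifnot(inherits(x, "expression_set"))
  out <- bind_cols(tibble(feature_id = rownames(x$values)),
                   as_tibble(x$values, .name_repair = "minimal"))
  readr::write_tsv(out, path)
  readr::write_tsv(x$groups, groups_path)
  invisible(x)
}

#' Read and write rank databases
#'
#' Two files: an instance metadata TSV (`instance_id`, `perturbagen`,
#' `dose`, `cell`) and a ranks TSV (first column probe id, one integer
#' column per instance). Every instance column must be a permutation of
#' `1..n_probes` — rank 1 meaning most up-regulated by the treatment — and
#' any violation is reported with the offending instance named.
#'
#' @param meta_path Instance metadata TSV.
#' @param ranks_path Probe x instance rank TSV.
#' @return A [rank_db()].
#' @export
read_rank_database <- function(meta_path, ranks_path) {
  meta <- read_tsv_strict(meta_path)
  need <- c("instance_id", "perturbagen", "dose", "cell")
  if (!all(need %in% names(meta))) {
    abort(paste0("metadata TSV needs columns: ", paste(need, collapse = ", ")))
  }
  df <- read_tsv_strict(ranks_path)
  pid <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(pid, names(df)[-1])
  rank_db(m, meta)
}

#' @rdname read_rank_database
#' @param db A `rank_db`.
#' @export
write_rank_database <- function(db, meta_path, ranks_path) {
  stopifnot(inherits(db, "rank_db"))
  readr::write_tsv(db$meta, meta_path)
  out <- bind_cols(tibble(probe_id = rownames(db$ranks)),
                   as_tibble(db$ranks, .name_repair = "minimal"))
  readr::write_tsv(out, ranks_path)
  invisible(db)
}

#' Read and write GRP tag lists
#'
#' The GRP dialect used for CMAP query uploads: one feature identifier per
#' line, no header. Blank lines and `#` comment lines are skipped; order is
#' preserved. An empty tag list is not a valid query and raises an error.
#'
#' @param path File path.
#' @return Character vector of feature ids, in file order.
#' @export
read_grp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort(paste0("'", basename(path), "': empty tag list is not a valid query."))
  }
  lines
}

#' @rdname read_grp
#' @param ids Character vector of feature ids.
#' @export
write_grp <- function(ids, path) {
  ids <- as.character(ids)
  if (length(ids) == 0) abort("refusing to write an empty GRP file.")
  writeLines(ids, path)
  invisible(ids)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene symbols. Members are deduplicated; a line with fewer
#' than three fields, or whose members vanish after deduplication of empty
#' strings, is an error reported with its line number.
#'
#' @param path File path.
#' @return A tibble with columns `set_name`, `description`, and `genes`
#'   (a list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("'", basename(path), "': no gene sets."))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::imap(parts, function(p, i) {
    if (length(p) < 3) {
      abort(paste0("GMT line ", i, ": fewer than 3 tab-separated fields."))
    }
    genes <- unique(p[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      abort(paste0("GMT line ", i, ": no gene members after deduplication."))
    }
    tibble(set_name = p[[1]], description = p[[2]], genes = list(genes))
  })
  out <- bind_rows(rows)
  check_unique(out$set_name, "gene-set name")
  out
}

#' @rdname read_gmt
#' @param collection Tibble as returned by `read_gmt()`.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set_name, description, genes) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(collection)
}

#' Read a probe-to-gene lookup table
#'
#' Two-column TSV (`probe_id`, `gene_symbol`). Probes with an empty or `NA`
#' gene symbol are treated as unmapped and dropped. A probe mapped to two
#' different symbols is an error; many probes per gene are expected.
#'
#' @param path File path.
#' @return Tibble with columns `probe_id`, `gene_symbol` (one row per
#'   mapped probe).
#' @export
read_probe_map <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2) abort("probe map TSV needs two columns: probe id, gene symbol.")
  map <- tibble(probe_id = as.character(df[[1]]),
                gene_symbol = as.character(df[[2]]))
  map <- map[!is.na(map$gene_symbol) & nzchar(map$gene_symbol), ]
  map <- distinct(map)
  check_unique(map$probe_id, "probe id mapped to more than one gene symbol")
  map
}

#' @rdname read_probe_map
#' @param map Tibble as returned by `read_probe_map()`.
#' @export
write_probe_map <- function(map, path) {
  readr::write_tsv(map[, c("probe_id", "gene_symbol")], path)
  invisible(map)
}

# shared strict TSV reader: no type guessing surprises, no name repair
read_tsv_strict <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  name_repair = "minimal")
}
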