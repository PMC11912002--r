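# Core containers and conventions: canonical chromosome labels, the
# -log10(p) transform, and validated summary-statistics tables.
#
# Coordinates are 1-based inclusive throughout (GFF/GTF and GWAS convention).
# BED-family inputs are converted at the reader boundary (see load_recomb()).

#' Normalise chromosome labels
#'
#' Strips any `"chr"` prefix and upper-cases the sex/mitochondrial
#' chromosomes, so UCSC-style (`chr7`, `chrX`) and Ensembl-style (`7`, `X`)
#' labels compare equal. `"M"` is mapped to `"MT"`.
#'
#' @param x Character (or coercible) vector of chromosome labels.
#' @return Character vector of normalised labels.
#' @examples
#' normalise_chrom(c("chr7", "X", "chrMT", "m"))
#' @export
normalise_chrom <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  special <- toupper(x) %in% c("X", "Y", "MT", "M")
  x[special] <- toupper(x[special])
  x[x == "M"] <- "MT"
  x
}

# Sort key: autosomes numerically, then X (23), Y (24), MT (25), then any
# other label alphabetically after those. Deterministic within one table.
chrom_rank <- function(x) {
  r <- suppressWarnings(as.numeric(x))
  r[x == "X"] <- 23
  r[x == "Y"] <- 24
  r[x == "MT"] <- 25
  unknown <- is.na(r)
  if (any(unknown)) {
    lv <- sort(unique(x[unknown]))
    r[unknown] <- 1000 + match(x[unknown], lv)
  }
  r
}

#' Display transform for p-values
#'
#' Computes `-log10(p)`, the y-axis of every locus scatter panel. `p = 0`
#' (seen in real summary statistics when p underflows double precision) is
#' capped at `cap` with a warning so axes stay finite.
#'
#' @param p Numeric vector of p-values in `[0, 1]`. `NA` passes through.
#' @param cap Value returned for `p = 0` (default 300, roughly the smallest
#'   p-value representable as a double).
#' @return Numeric vector of display values.
#' @examples
#' neglog10(c(1, 0.05, 1e-6))
#' @export
neglog10 <- function(p, cap = 300) {
  if (!is.numeric(p)) {
    abort("`p` must be numeric.", class = "locusviz_domain_error")
  }
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(
      sprintf("p-values must lie in [0, 1]; %d value(s) outside range (first: %g).",
              sum(bad), p[bad][1]),
      class = "locusviz_domain_error"
    )
  }
  out <- -log10(p)
  zero <- !is.na(p) & p == 0
  if (any(zero)) {
    warn(sprintf("%d p-value(s) equal to 0 capped at -log10(p) = %g.",
                 sum(zero), cap))
    out[zero] <- cap
  }
  out
}

# Internal constructor shared by the reader and the synthetic generator.
new_sumstats <- function(df, source = "memory", n_dropped = 0L,
                         column_map = NULL) {
  df <- as_tibble(df)
  structure(
    df,
    class = c("sumstats", class(df)),
    source = source,
    n_dropped = as.integer(n_dropped),
    column_map = column_map
  )
}

#' Coerce a data frame to a validated summary-statistics table
#'
#' Applies the same validation as [read_summary_stats()] to an in-memory data
#' frame: chromosome labels are normalised, rows with missing chromosome or
#' position, unparseable positions, or p-values outside `[0, 1]` are dropped
#' (with the count recorded in the `n_dropped` attribute), and rows are sorted
#' by `(chrom, pos)`.
#'
#' @param df Data frame with at least `chrom`, `pos` and `p` columns; optional
#'   `id`, `direction` (effect sign in -1/0/+1, or "+"/"-") and `typed`
#'   (logical typed-vs-imputed flag) columns are kept.
#' @param source Provenance string stored on the result.
#' @return A `sumstats` tibble.
#' @examples
#' as_sumstats(data.frame(chrom = "1", pos = c(30, 10), p = c(0.5, 1e-8)))
#' @export
as_sumstats <- function(df, source = "memory") {
  req <- c("chrom", "pos", "p")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "locusviz_config_error")
  }
  df <- as_tibble(df)
  n_in <- nrow(df)

  df$chrom <- normalise_chrom(df$chrom)
  df$pos <- suppressWarnings(as.numeric(df$pos))
  df$p <- suppressWarnings(as.numeric(df$p))
  if ("id" %in% names(df)) df$id <- as.character(df$id)
  if ("direction" %in% names(df)) df$direction <- parse_direction(df$direction)
  if ("typed" %in% names(df)) df$typed <- parse_typed(df$typed)

  keep <- !is.na(df$chrom) & nzchar(df$chrom) &
    !is.na(df$pos) & df$pos >= 1 & df$pos == floor(df$pos) &
    !is.na(df$p) & df$p >= 0 & df$p <= 1
  df <- df[keep, , drop = FALSE]
  df <- df[order(chrom_rank(df$chrom), df$pos), , drop = FALSE]

  canonical <- intersect(c("chrom", "pos", "p", "id", "direction", "typed"),
                         names(df))
  df <- df[, c(canonical, setdiff(names(df), canonical)), drop = FALSE]
  new_sumstats(df, source = source, n_dropped = n_in - nrow(df))
}

parse_direction <- function(x) {
  if (is.numeric(x)) return(sign(x))
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  out[x %in% c("+", "+1", "1", "up")] <- 1
  out[x %in% c("-", "-1", "down")] <- -1
  out[x %in% c("0", ".", "")] <- 0
  suppress <- suppressWarnings(as.numeric(x))
  out[is.na(out) & !is.na(suppress)] <- sign(suppress[is.na(out) & !is.na(suppress)])
  out
}

parse_typed <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "typed", "genotyped", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "imputed", "no")] <- FALSE
  out
}

# Resolve a column map given as a named character vector (canonical -> source
# column name) or a path to a YAML/JSON file holding the same mapping.
resolve_column_map <- function(column_map) {
  if (is.null(column_map)) {
    # canonical names; optional fields are ignored when absent from the header
    return(c(chrom = "chrom", pos = "pos", p = "p", id = "id",
             direction = "direction", typed = "typed"))
  }
  if (is.character(column_map) && length(column_map) == 1 &&
      is.null(names(column_map)) && file.exists(column_map)) {
    ext <- tolower(tools::file_ext(column_map))
    parsed <- if (ext == "json") {
      jsonlite::read_json(column_map, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(column_map)
    }
    column_map <- unlist(parsed)
  }
  column_map <- unlist(column_map)
  if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
    abort("`column_map` must be named: canonical field -> source column.",
          class = "locusviz_config_error")
  }
  missing_req <- setdiff(c("chrom", "pos", "p"), names(column_map))
  if (length(missing_req)) {
    abort(sprintf("column_map must name column(s): %s",
                  paste(missing_req, collapse = ", ")),
          class = "locusviz_config_error")
  }
  column_map
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
}

#' Read GWAS summary statistics from delimited text
#'
#' Loads a (possibly multi-million-row) summary-statistics file in bounded
#' chunks, maps source columns to the canonical fields via `column_map`,
#' validates each row, and returns a sorted [as_sumstats()] table. Rows with
#' missing chromosome/position, non-integer or unparseable positions, or
#' p-values outside `[0, 1]` are dropped; the count is stored in the
#' `n_dropped` attribute and reported with a message.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical fields
#'   (`chrom`, `pos`, `p`, optionally `id`, `direction`, `typed`) to the
#'   source column names, or a path to a YAML/JSON file holding that mapping.
#'   Defaults to the canonical names themselves.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param chunk_size Rows per pass (default 500000); memory use is bounded by
#'   chunk, not file, size.
#' @return A `sumstats` tibble sorted by `(chrom, pos)`.
#' @seealso [as_sumstats()], [quickpeak()], [locus()]
#' @export
read_summary_stats <- function(path, column_map = NULL, delim = NULL,
                               chunk_size = 500000L) {
  if (!file.exists(path)) {
    abort(sprintf("summary statistics file not found: %s", path),
          class = "locusviz_io_error")
  }
  if (file.size(path) == 0 ||
      length(readLines(path, n = 1L, warn = FALSE)) == 0) {
    abort(sprintf("empty summary statistics file: %s", path),
          class = "locusviz_empty_input_error")
  }
  column_map <- resolve_column_map(column_map)
  delim <- delim %||% sniff_delim(path)

  header <- strsplit(readLines(path, n = 1L, warn = FALSE), delim,
                     fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  absent <- !(column_map %in% header)
  required_absent <- intersect(names(column_map)[absent],
                               c("chrom", "pos", "p"))
  if (length(required_absent)) {
    abort(sprintf(
      "column '%s' (mapped to field '%s') not found in header of %s",
      column_map[required_absent[1]], required_absent[1], path),
      class = "locusviz_config_error")
  }
  # optional mapped columns missing from the header are silently ignored
  column_map <- column_map[!absent]

  chunks <- list()
  dropped <- 0L
  cb <- function(chunk, pos_idx) {
    got <- intersect(unname(column_map), names(chunk))
    chunk <- chunk[, got, drop = FALSE]
    names(chunk) <- names(column_map)[match(got, unname(column_map))]
    ss <- as_sumstats(chunk, source = path)
    dropped <<- dropped + attr(ss, "n_dropped")
    chunks[[length(chunks) + 1L]] <<- as_tibble(ss)
  }
  readr::read_delim_chunked(
    path,
    callback = readr::DataFrameCallback$new(cb),
    delim = delim,
    chunk_size = chunk_size,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE,
    trim_ws = TRUE
  )
  if (!length(chunks)) {
    abort(sprintf("no data rows in %s", path),
          class = "locusviz_empty_input_error")
  }
  df <- bind_rows(chunks)
  df <- df[order(chrom_rank(df$chrom), df$pos), , drop = FALSE]
  if (dropped > 0) {
    inform(sprintf("read_summary_stats: dropped %d malformed row(s) from %s",
                   dropped, basename(path)))
  }
  new_sumstats(df, source = path, n_dropped = dropped,
               column_map = column_map)
}

#' Write summary statistics as TSV
#'
#' Canonical columns only; round-trips exactly through
#' [read_summary_stats()].
#'
#' @param stats A `sumstats` tibble (or any data frame accepted by
#'   [as_sumstats()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  cols <- intersect(c("chrom", "pos", "p", "id", "direction", "typed"),
                    names(stats))
  readr::write_tsv(as_tibble(stats)[, cols, drop = FALSE], path)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("# GWAS summary statistics: %s variants on %d chromosome(s)",
              format(nrow(x), big.mark = ","),
              length(unique(x$chrom))), "\n")
  nd <- attr(x, "n_dropped")
  if (!is.null(nd) && nd > 0) {
    cat(sprintf("# (%d malformed row(s) dropped on load)\n", nd))
  }
  NextMethod()
}

#' @rdname glance.locus
#' @method glance sumstats
#' @export
glance.sumstats <- function(x, ...) {
  tibble(
    n_variants = nrow(x),
    n_chrom = length(unique(x$chrom)),
    min_p = if (nrow(x)) min(x$p) else NA_real_,
    n_dropped = attr(x, "n_dropped") %||% 0L,
    source = attr(x, "source") %||% NA_character_
  )
}
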