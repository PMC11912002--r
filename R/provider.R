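# Pluggable data providers with a persistent on-disk cache.
#
# Remote LD / eQTL / recombination services are slow and rate-limited, so
# every provider fetch is memoised to a cache directory keyed by the query.
# Tests and batch runs use file-backed providers; live network clients only
# need to supply a `fetch` function honouring the same contract.

#' Create a cached data provider
#'
#' A provider wraps a `fetch(key)` function with a persistent cache: the
#' first call for a key delegates to `fetch` and stores the payload under
#' `cache_dir`; later calls for the same key — including from a new R
#' process pointed at the same directory — are served from disk without
#' touching `fetch`.
#'
#' @param fetch Function of one string `key` returning any R payload.
#' @param cache_dir Directory for the persistent cache; created if missing.
#'   `NULL` disables caching (every call fetches).
#' @param name Label used in error messages.
#' @return A `locusviz_provider` object.
#' @examples
#' pr <- provider(function(key) toupper(key), cache_dir = tempfile())
#' cached_fetch(pr, "rs123")
#' @export
provider <- function(fetch, cache_dir = NULL, name = "provider") {
  stopifnot(is.function(fetch))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  structure(list(fetch = fetch, cache_dir = cache_dir, name = name),
            class = "locusviz_provider")
}

# Filesystem-safe cache filename: sanitised key prefix plus a position-
# weighted checksum so distinct keys that sanitise alike stay distinct.
cache_key_token <- function(key) {
  stopifnot(is.character(key), length(key) == 1)
  safe <- substr(gsub("[^A-Za-z0-9._-]", "_", key), 1, 80)
  codes <- utf8ToInt(key)
  chk <- sum(as.numeric(codes) * seq_along(codes)) %% 1e9
  sprintf("%s-%09.0f", safe, chk)
}

#' Fetch a payload through a provider's cache
#'
#' @param provider A [provider()].
#' @param key Query key (single string).
#' @return The payload. Fetch failures are re-raised with the key in the
#'   message; an unreadable (corrupt) cache entry is bypassed with a warning
#'   and re-fetched.
#' @export
cached_fetch <- function(provider, key) {
  stopifnot(inherits(provider, "locusviz_provider"))
  cache_file <- NULL
  if (!is.null(provider$cache_dir)) {
    cache_file <- file.path(provider$cache_dir,
                            paste0(cache_key_token(key), ".rds"))
    if (file.exists(cache_file)) {
      payload <- tryCatch(readRDS(cache_file), error = function(e) {
        warn(sprintf("corrupt cache entry for key '%s'; re-fetching.", key))
        NULL
      })
      if (!is.null(payload)) return(payload$value)
    }
  }
  payload <- tryCatch(provider$fetch(key), error = function(e) {
    abort(sprintf("%s fetch failed for key '%s': %s", provider$name, key,
                  conditionMessage(e)),
          class = "locusviz_fetch_error", parent = e)
  })
  if (!is.null(cache_file)) {
    # wrap so a legitimately-NULL payload is still a cache hit
    saveRDS(list(value = payload), cache_file)
  }
  payload
}

#' Empty a provider's persistent cache
#'
#' @param provider A [provider()].
#' @return Number of entries removed, invisibly.
#' @export
clear_cache <- function(provider) {
  stopifnot(inherits(provider, "locusviz_provider"))
  if (is.null(provider$cache_dir)) return(invisible(0L))
  files <- list.files(provider$cache_dir, pattern = "\\.rds$",
                      full.names = TRUE)
  unlink(files)
  invisible(length(files))
}

#' File-backed providers for LD, recombination and eQTL data
#'
#' Convenience constructors wrapping the file readers in the provider
#' contract, for batch workflows that pre-download their data (the
#' recommended setup for plotting many loci). The key is the file path.
#'
#' @param cache_dir Cache directory (see [provider()]).
#' @return A `locusviz_provider`.
#' @export
ld_file_provider <- function(cache_dir = NULL) {
  provider(function(key) load_ld(key), cache_dir = cache_dir,
           name = "ld_file")
}

#' @rdname ld_file_provider
#' @export
recomb_file_provider <- function(cache_dir = NULL) {
  provider(function(key) load_recomb(key), cache_dir = cache_dir,
           name = "recomb_file")
}
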