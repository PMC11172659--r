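#' @importFrom stats median pchisq qchisq rbinom rnorm runif sd var quantile setNames
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hw <- function(..., call. = FALSE) stop(..., call. = call.)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_hw(sprintf("`%s` must be a single number in [0, 1], got %s",
                    name, paste(format(x), collapse = ",")))
  invisible(x)
}

check_no_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_hw(sprintf("duplicate %s ID(s): %s", what,
                    paste(head(dup, 5L), collapse = ", ")))
  invisible(ids)
}

is_symmetric_tol <- function(m, tol = 1e-10) {
  max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

#' Write a table atomically
#'
#' Writes to a temporary file in the destination directory and renames it
#' into place, so readers never observe a half-written file.
#' @noRd
write_tsv_atomic <- function(df, path, ...) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  data.table::fwrite(df, tmp, sep = "\t", quote = FALSE, na = "NA", ...)
  file.rename(tmp, path)
  invisible(path)
}

## Run `expr` with a private RNG stream seeded by `seed`, restoring the
## caller's stream afterwards. All package-level randomness funnels through
## this so that pipelines are reproducible end to end.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
  }
  expr
}

## Derive a child seed below 2^31 from a master seed and a label.
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + as.double(k) * 9973) %% 2147483629 + 1
}
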