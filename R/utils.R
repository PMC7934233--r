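#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Each stochastic operation derives its own sub-seed from that master seed
#' and a short operation label, so adding a stage never perturbs the draws
#' of another stage.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the consuming operation.
#' @return an integer in [0, 2^31 - 2] suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647           # 2^31 - 1, keeps the result a valid R integer
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# run `expr` with a derived seed, restoring the caller's RNG state afterwards
with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, label))
  expr
}

#' Write a table atomically
#'
#' Writes to a temporary file in the destination directory and renames it
#' into place, so a failed write never leaves a partial output behind.
#'
#' @param x data.frame or matrix to write.
#' @param path destination path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_tsv_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  data.table::fwrite(as.data.frame(x), tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  ok <- TRUE
  invisible(path)
}

write_lines_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  ok <- TRUE
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
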