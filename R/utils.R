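`%||%` <- function(a, b) if (is.null(a)) b else a

# Set the RNG seed for the calling function only; global RNG state is
# restored on exit. seed = NULL leaves the RNG stream untouched.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

# Draw n sub-seeds deterministically from the current RNG stream; used to
# hand independent, reproducible seeds to nested Monte-Carlo stages.
draw_subseeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Standard chance-corrected agreement between two labelings of the same
#' items; 1 means identical partitions (up to label names), 0 is the
#' expected agreement of independent random partitions.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that
#' parse as numbers are returned numeric; the strings TRUE/FALSE become
#' logical; comma-separated values become vectors.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key = value'): ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (length(parts) > 0 && !anyNA(num)) {
      cfg[[key]] <- num
    } else if (all(parts %in% c("TRUE", "FALSE"))) {
      cfg[[key]] <- as.logical(parts)
    } else {
      cfg[[key]] <- if (length(parts) == 1L) val else parts
    }
  }
  cfg
}
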