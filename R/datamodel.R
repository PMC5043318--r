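#' Construct a performance (an ordered sequence of phrase records)
#'
#' A performance is the central analysis object: the ordered phrases of
#' one uninterrupted singing bout of one bird. Each phrase carries a
#' phrase-type label and an (optionally empty) ordered list of motif
#' labels. Motif order within a phrase is preserved for display but is
#' ignored by all interval statistics, which depend only on presence.
#'
#' @param phrase_types character vector of phrase-type labels, one per
#'   phrase, in performance order.
#' @param motifs list of character vectors (one per phrase) of motif
#'   labels; `NULL` means no motif annotation (all empty).
#' @param bird_id identifier for the bird/recording.
#' @return an object of class `performance` with fields `bird_id`,
#'   `phrase_type` and `motifs`; phrase indices are implicitly 1..N.
#' @export
performance <- function(phrase_types, motifs = NULL, bird_id = "bird") {
  phrase_types <- as.character(phrase_types)
  n <- length(phrase_types)
  if (n < 1) stop("a performance needs at least one phrase")
  if (is.null(motifs)) motifs <- rep(list(character()), n)
  if (length(motifs) != n) stop("motifs must have one entry per phrase")
  motifs <- lapply(motifs, as.character)
  perf <- structure(
    list(bird_id = as.character(bird_id)[1],
         phrase_type = phrase_types,
         motifs = motifs),
    class = "performance")
  validate_performance(perf)
  perf
}

validate_performance <- function(perf) {
  stopifnot(inherits(perf, "performance"))
  if (any(!nzchar(perf$phrase_type)) || anyNA(perf$phrase_type)) {
    stop("phrase_type labels must be non-empty")
  }
  bad <- vapply(perf$motifs, function(m) anyNA(m) || any(!nzchar(m)),
                logical(1))
  if (any(bad)) {
    stop("empty motif labels in phrase(s) ", paste(which(bad), collapse = ", "))
  }
  invisible(perf)
}

#' @export
print.performance <- function(x, ...) {
  cat("<performance> bird:", x$bird_id, "-", length(x$phrase_type),
      "phrases,", length(unique(x$phrase_type)), "phrase types,",
      length(unique(unlist(x$motifs))), "motif types\n")
  invisible(x)
}

#' @export
length.performance <- function(x) length(x$phrase_type)

#' Motif alphabet of a performance
#' @param perf a [performance()].
#' @return sorted character vector of distinct motif labels.
#' @export
motif_alphabet <- function(perf) {
  sort(unique(unlist(perf$motifs)))
}

# ---- delimited-text serialization ------------------------------------------

# Motif cells are motif_sep-joined; occurrences of the separator or of the
# escape character inside a label are backslash-escaped so round trips are
# exact. Cells are scanned character-wise (labels are short).
escape_motif_cell <- function(labels, motif_sep) {
  esc <- gsub("\\", "\\\\", labels, fixed = TRUE)
  esc <- gsub(motif_sep, paste0("\\", motif_sep), esc, fixed = TRUE)
  paste(esc, collapse = motif_sep)
}

split_motif_cell <- function(cell, motif_sep) {
  if (is.na(cell) || !nzchar(cell)) return(character())
  chars <- strsplit(cell, "", fixed = TRUE)[[1]]
  out <- character()
  buf <- character()
  escaped <- FALSE
  for (ch in chars) {
    if (escaped) {
      buf <- c(buf, ch)
      escaped <- FALSE
    } else if (ch == "\\") {
      escaped <- TRUE
    } else if (ch == motif_sep) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  c(out, paste(buf, collapse = ""))
}

#' Read a performance table from delimited text
#'
#' Expects a UTF-8 delimited file with a header naming the columns
#' `index`, `phrase_type` and `motifs` (the on-disk analogue of a motif
#' matrix: one phrase per row, motif labels joined by `motif_sep` within
#' the motif cell). Lines starting with `#` are comments. Indices must be
#' consecutive 1..N in file order.
#'
#' @param path file path.
#' @param sep column delimiter (default comma).
#' @param motif_sep within-cell motif delimiter (default `";"`).
#' @param bird_id bird identifier to attach; default is the file name
#'   without extension.
#' @return a [performance()].
#' @export
read_performance <- function(path, sep = ",", motif_sep = ";",
                             bird_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, sep = sep, comment.char = "#",
                         colClasses = "character", check.names = FALSE)
  required <- c("index", "phrase_type", "motifs")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("performance table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  idx <- suppressWarnings(as.integer(tab$index))
  if (anyNA(idx)) stop("performance table format error: non-integer index")
  bad <- which(idx != seq_along(idx))
  if (length(bad) > 0) {
    stop("performance table validation error: non-consecutive index at row ",
         bad[1], " (found ", idx[bad[1]], ", expected ", bad[1], ")")
  }
  motifs <- lapply(tab$motifs, split_motif_cell, motif_sep = motif_sep)
  performance(tab$phrase_type, motifs,
              bird_id = bird_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a performance table as delimited text
#'
#' Inverse of [read_performance()]: the written file re-parses to a
#' performance with identical fields. Labels containing the column or
#' motif delimiter are quoted/escaped.
#'
#' @param perf a [performance()].
#' @param path output file path.
#' @param sep,motif_sep delimiters, as in [read_performance()].
#' @return `path`, invisibly.
#' @export
write_performance <- function(perf, path, sep = ",", motif_sep = ";") {
  validate_performance(perf)
  cells <- vapply(perf$motifs, escape_motif_cell, character(1),
                  motif_sep = motif_sep)
  tab <- data.frame(index = seq_along(perf$phrase_type),
                    phrase_type = perf$phrase_type,
                    motifs = cells,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write performance table to ", path)
  invisible(path)
}

# ---- motif map --------------------------------------------------------------

#' Derive the phrase-type to motif-set mapping of a performance
#'
#' Every record of a phrase type must carry the same motif set (the
#' curated annotation is per type); inconsistencies are reported with the
#' offending phrase indices.
#'
#' @param perf a [performance()].
#' @return an object of class `motif_map`: a named list mapping each
#'   phrase type present to its sorted motif-label set.
#' @export
derive_motif_map <- function(perf) {
  validate_performance(perf)
  types <- unique(perf$phrase_type)
  map <- vector("list", length(types))
  names(map) <- types
  for (ty in types) {
    idx <- which(perf$phrase_type == ty)
    sets <- lapply(perf$motifs[idx], function(m) sort(unique(m)))
    ref <- sets[[1]]
    differs <- !vapply(sets, identical, logical(1), y = ref)
    if (any(differs)) {
      stop("inconsistent motif sets for phrase type '", ty,
           "' at indices ", idx[1], " and ",
           paste(idx[differs], collapse = ", "))
    }
    map[[ty]] <- ref
  }
  structure(map, class = "motif_map")
}

#' Construct a motif map directly
#' @param map named list: phrase type -> character vector of motif labels.
#' @return a `motif_map`.
#' @export
motif_map <- function(map) {
  stopifnot(is.list(map), !is.null(names(map)), all(nzchar(names(map))))
  map <- lapply(map, function(m) sort(unique(as.character(m))))
  structure(map, class = "motif_map")
}

#' @export
print.motif_map <- function(x, ...) {
  cat("<motif_map>", length(x), "phrase types\n")
  for (ty in names(x)) {
    cat("  ", ty, ": {", paste(x[[ty]], collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

# ---- transition matrix ------------------------------------------------------

#' Construct a phrase-type transition matrix
#'
#' Holds bigram transition counts and row-normalized probabilities over an
#' ordered state set. Rows with zero outgoing count are dead ends (their
#' probability row is all zero and they are flagged); the optional `init`
#' distribution is used to (re)start synthetic sequences.
#'
#' @param counts square non-negative matrix of observed transitions
#'   (for synthesized matrices, an indicator of admissible transitions).
#' @param states character vector of state labels; defaults to the
#'   dimnames of `counts`.
#' @param init optional initial/restart distribution over states;
#'   defaults to uniform.
#' @return an object of class `transition_matrix` with fields `states`,
#'   `counts`, `probs`, `init` and `dead_ends` (logical per row).
#' @export
transition_matrix <- function(counts, states = NULL, init = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  states <- as.character(states %||% rownames(counts) %||%
                           as.character(seq_len(nrow(counts))))
  if (length(states) != nrow(counts)) stop("states/counts shape mismatch")
  dimnames(counts) <- list(states, states)
  rs <- rowSums(counts)
  dead <- rs == 0
  probs <- counts
  probs[!dead, ] <- counts[!dead, , drop = FALSE] / rs[!dead]
  probs[dead, ] <- 0
  init <- init %||% rep(1 / length(states), length(states))
  if (length(init) != length(states) || any(init < 0) ||
      abs(sum(init) - 1) > 1e-9) {
    stop("init must be a probability distribution over states")
  }
  structure(
    list(states = states, counts = counts, probs = probs,
         init = as.numeric(init / sum(init)), dead_ends = unname(dead)),
    class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix>", length(x$states), "states,",
      sum(x$counts > 0), "non-zero entries",
      if (any(x$dead_ends)) paste0("(", sum(x$dead_ends), " dead-end row(s))"),
      "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Write a transition matrix as tabular text
#'
#' Writes the probability matrix with states as header row/column, plus a
#' commented structured dump of the counts so the file is self-contained.
#'
#' @param tm a [transition_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(tm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# transition probabilities (rows: from, cols: to)", con)
  utils::write.csv(as.data.frame(tm$probs), con, row.names = TRUE)
  writeLines("# counts:", con)
  for (i in seq_along(tm$states)) {
    writeLines(paste0("# ", tm$states[i], ": ",
                      paste(tm$counts[i, ], collapse = ",")), con)
  }
  invisible(path)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the probability matrix for eigenvalue 1,
#' normalized to sum to one. Requires an irreducible chain (no dead-end
#' rows).
#'
#' @param tm a [transition_matrix()].
#' @return numeric vector over `tm$states`.
#' @export
stationary_distribution <- function(tm) {
  if (any(tm$dead_ends)) stop("chain has dead-end rows; no stationary law")
  e <- eigen(t(tm$probs))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}
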