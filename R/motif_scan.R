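#' Parse a degenerate gapped RNA motif
#'
#' Grammar: a sequence of single bases (`A`, `C`, `G`, `U`), parenthesized
#' alternatives like `(A/G/U)`, and at most one variable-length spacer
#' `N<a>-<b>` (also written `N<a>` for a fixed gap). Underscores, whitespace
#' and en-dashes in the input are normalized away, so the printed forms of
#' the MEX3 recognition elements - e.g. `(A/G/U)(G/U)AGN0-8U(U/A/C)UA` -
#' parse directly. Positions before the spacer form the head, positions after
#' it the tail; a spacer-free motif has an empty tail and gap 0-0.
#'
#' @param text motif string.
#' @return An object of class `motif_pattern`: list with `head` and `tail`
#'   (lists of allowed-base character vectors), `gap_min`, `gap_max`.
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[–—]", "-", text)
  s <- gsub("[_[:space:]]", "", s)
  s <- gsub("′", "", s)   # prime marks from 5'/3' annotations
  s <- toupper(s)
  tokens <- list(); spacer <- NULL; after_spacer <- FALSE
  head <- list(); tail <- list()
  push <- function(set) {
    if (after_spacer) tail[[length(tail) + 1L]] <<- set
    else head[[length(head) + 1L]] <<- set
  }
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      j <- regexpr(")", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("motif grammar error: unclosed '('")
      inner <- substr(s, i + 1L, i + j - 2L)
      alts <- strsplit(inner, "/", fixed = TRUE)[[1]]
      alts[alts == "T"] <- "U"
      if (length(alts) == 0L || any(!alts %in% c("A", "C", "G", "U")))
        stop("motif grammar error: bad alternative group '(", inner, ")'")
      push(unique(alts))
      i <- i + j
    } else if (ch == "N" && i < n && grepl("^[0-9]", substr(s, i + 1L, i + 1L))) {
      m <- regmatches(substr(s, i, n),
                      regexpr("^N([0-9]+)(-([0-9]+))?", substr(s, i, n)))
      if (!is.null(spacer)) stop("motif grammar error: more than one N spacer")
      nums <- as.integer(strsplit(gsub("^N", "", m), "-")[[1]])
      gap_min <- nums[1]
      gap_max <- if (length(nums) > 1L) nums[2] else nums[1]
      if (gap_max < gap_min) stop("motif grammar error: spacer max below min")
      spacer <- c(gap_min, gap_max)
      after_spacer <- TRUE
      i <- i + nchar(m)
    } else if (ch %in% c("A", "C", "G", "U", "T")) {
      push(if (ch == "T") "U" else ch)
      i <- i + 1L
    } else {
      stop("motif grammar error: unexpected character '", ch, "'")
    }
  }
  if (length(head) == 0L) stop("motif grammar error: empty head")
  if (!is.null(spacer) && length(tail) == 0L)
    stop("motif grammar error: spacer with empty tail")
  structure(list(head = head, tail = tail,
                 gap_min = if (is.null(spacer)) 0L else spacer[1],
                 gap_max = if (is.null(spacer)) 0L else spacer[2]),
            class = "motif_pattern")
}

#' Canonical string form of a motif pattern
#'
#' @param pattern a `motif_pattern`.
#' @return Character string; `parse_pattern()` of the result reproduces the
#'   pattern.
#' @export
pattern_to_string <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  fmt <- function(sets) paste(vapply(sets, function(x)
    if (length(x) == 1L) x else paste0("(", paste(x, collapse = "/"), ")"),
    character(1)), collapse = "")
  if (length(pattern$tail) == 0L) return(fmt(pattern$head))
  paste0(fmt(pattern$head), "N", pattern$gap_min, "-", pattern$gap_max,
         fmt(pattern$tail))
}

match_block <- function(chars, sets, at) {
  for (k in seq_along(sets)) {
    if (!chars[at + k - 1L] %in% sets[[k]]) return(FALSE)
  }
  TRUE
}

#' Scan an RNA sequence for a degenerate gapped motif
#'
#' Enumerates every (start, gap length) combination that matches, on the
#' given strand only (5' to 3'; mRNA substrates are single-stranded, so no
#' reverse complement is considered). Overlapping matches and multiple gap
#' lengths at one start are all reported - this multiplicity is exactly what
#' produces several recognition registers in longer substrate fragments.
#'
#' @param seq an [rna_sequence()] (or a plain string, normalized via
#'   [rna_sequence()]).
#' @param pattern a `motif_pattern` from [parse_pattern()].
#' @return data.frame with 1-based inclusive columns `start`, `gap_len`,
#'   `end`, `matched_text`, sorted by (start, gap_len).
#' @export
scan_sequence <- function(seq, pattern) {
  if (!inherits(seq, "rna_sequence")) seq <- rna_sequence(seq)
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- strsplit(seq$bases, "")[[1]]
  L <- length(chars)
  hl <- length(pattern$head); tl <- length(pattern$tail)
  out <- list()
  max_start <- L - hl - (if (tl > 0L) pattern$gap_min + tl else 0L) + 1L
  for (s in seq_len(max(max_start, 0L))) {
    if (!match_block(chars, pattern$head, s)) next
    if (tl == 0L) {
      out[[length(out) + 1L]] <- c(s, 0L, s + hl - 1L)
      next
    }
    for (g in pattern$gap_min:pattern$gap_max) {
      t0 <- s + hl + g
      if (t0 + tl - 1L > L) break
      if (match_block(chars, pattern$tail, t0))
        out[[length(out) + 1L]] <- c(s, g, t0 + tl - 1L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), gap_len = integer(0),
                      end = integer(0), matched_text = character(0)))
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], gap_len = m[, 2], end = m[, 3])
  df <- df[order(df$start, df$gap_len), , drop = FALSE]
  df$matched_text <- substring(seq$bases, df$start, df$end)
  rownames(df) <- NULL
  df
}

#' Scan several sequences against several motifs
#'
#' @param seqs list of [rna_sequence()] (plain strings accepted).
#' @param patterns list of `motif_pattern` (plain strings accepted and
#'   parsed).
#' @return data.frame with columns `seq_id`, `pattern`, `start`, `gap_len`,
#'   `end`, `matched_text`; zero rows if nothing matches or the pattern list
#'   is empty.
#' @export
scan_report <- function(seqs, patterns) {
  if (inherits(seqs, "rna_sequence") || is.character(seqs)) seqs <- list(seqs)
  if (inherits(patterns, "motif_pattern") || (is.character(patterns) &&
                                              length(patterns) == 1L))
    patterns <- list(patterns)
  seqs <- lapply(seqs, function(s) if (inherits(s, "rna_sequence")) s else rna_sequence(s))
  patterns <- lapply(patterns, function(p)
    if (inherits(p, "motif_pattern")) p else parse_pattern(p))
  rows <- list()
  for (s in seqs) {
    for (p in patterns) {
      hits <- scan_sequence(s, p)
      if (nrow(hits) > 0L)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(seq_id = s$id, pattern = pattern_to_string(p),
                     stringsAsFactors = FALSE), hits)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(seq_id = character(0), pattern = character(0),
                      start = integer(0), gap_len = integer(0),
                      end = integer(0), matched_text = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The two MEX3-family RNA recognition elements
#'
#' Convenience accessors for the two degenerate recognition motifs used to
#' locate candidate binding fragments in 3'UTR sequences: the worm-derived
#' element `(A/G/U)(G/U)AGN0-8U(U/A/C)UA` and the human-paralog element
#' `(A/G/U)(G/U)AGN0-8(A/G/U)(A/U)(A/U)(A/G/U)`.
#'
#' @return A named list of two `motif_pattern` objects (`ce_element`,
#'   `hs_element`).
#' @export
mex3_recognition_elements <- function() {
  list(ce_element = parse_pattern("(A/G/U)(G/U)AGN0-8U(U/A/C)UA"),
       hs_element = parse_pattern("(A/G/U)(G/U)AGN0-8(A/G/U)(A/U)(A/U)(A/G/U)"))
}
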