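#' GC content of a sequence or of selected positions
#'
#' `(G + C) / (A + T + G + C)` over the selected positions; `N` bases are
#' excluded from both numerator and denominator. When no counted base
#' remains the fraction is undefined and `NA` is returned.
#'
#' @param seq A single DNA string.
#' @param positions Optional 1-based positions to restrict to.
#' @return Fraction in `[0, 1]`, or `NA_real_` for an empty effective set.
#' @export
#' @examples
#' gc_content("ACGT")   # 0.5
#' gc_content("AANN")   # 0 (denominator 2)
gc_content <- function(seq, positions = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (!is.null(positions)) {
    if (length(positions) == 0) return(NA_real_)
    stopifnot(all(positions >= 1), all(positions <= length(chars)))
    chars <- chars[positions]
  }
  gc <- sum(chars %in% c("G", "C"))
  at <- sum(chars %in% c("A", "T"))
  if (gc + at == 0) return(NA_real_)
  gc / (gc + at)
}

# Resolve sequence-set arguments to a character vector.
as_sequences <- function(x) {
  if (inherits(x, "tss_dataset")) return(x$sequences)
  if (methods::is(x, "DNAStringSet")) return(as.character(x))
  stopifnot(is.character(x))
  x
}

#' GC content of a midpoint-relative slice across sequences
#'
#' Computes the per-sequence GC fraction over a midpoint-relative slice
#' (e.g. `c(20, 120)` for the +20..+120 bp downstream region, read as the
#' half-open interval `[+20, +120)`) and the group mean. With
#' `slice = NULL` the whole window is used.
#'
#' @param x A [tss_dataset()], `DNAStringSet`, or character vector of
#'   equal-length sequences.
#' @param slice `c(from, to)` midpoint-relative half-open interval, or
#'   `NULL` for the whole sequence.
#' @return An object of class `gc_report`: `per_sequence` fractions,
#'   `mean`, `n`, and the slice.
#' @export
regional_gc <- function(x, slice = NULL) {
  seqs <- as_sequences(x)
  l <- unique(nchar(seqs))
  if (length(l) != 1) stop("sequences differ in length")
  positions <- NULL
  if (!is.null(slice)) {
    stopifnot(length(slice) == 2, slice[2] > slice[1])
    if (slice[1] < -l / 2 || slice[2] > l / 2) {
      stop(sprintf("slice [%d, %d) outside window [-%d, %d)", slice[1],
                   slice[2], l / 2, l / 2))
    }
    positions <- rel_to_index(slice[1]:(slice[2] - 1), l)
  }
  per <- vapply(seqs, gc_content, 0, positions = positions, USE.NAMES = FALSE)
  if (inherits(x, "tss_dataset")) names(per) <- x$ids
  structure(list(per_sequence = per, mean = mean(per, na.rm = TRUE),
                 n = length(per), slice = slice),
            class = "gc_report")
}

#' @export
print.gc_report <- function(x, ...) {
  region <- if (is.null(x$slice)) "whole window" else
    sprintf("[%+d, %+d)", x$slice[1], x$slice[2])
  cat(sprintf("GC report (%s): mean %.4f over %d sequence(s)\n",
              region, x$mean, x$n))
  invisible(x)
}

#' Pooled GC content at saliency-important positions
#'
#' Pools the G/C and A/T counts at each sequence's important positions
#' across the whole group and reports the count-weighted fraction
#' `(sum G + sum C) / (sum counted)` -- appropriate because important sets
#' differ in size between sequences. If every important set is empty the
#' value is `NA`.
#'
#' @param x Sequences as in [regional_gc()].
#' @param important A list of 1-based position vectors, one per sequence
#'   (as returned by [call_important_positions()] on a score matrix).
#' @return A `gc_report` whose `mean` is the pooled fraction and whose
#'   `per_sequence` holds the per-sequence fractions (`NA` when empty).
#' @export
gc_at_important_positions <- function(x, important) {
  seqs <- as_sequences(x)
  stopifnot(length(important) == length(seqs))
  gc <- 0L
  total <- 0L
  per <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    pos <- important[[i]]
    per[i] <- gc_content(seqs[i], positions = pos)
    if (length(pos)) {
      chars <- strsplit(toupper(seqs[i]), "", fixed = TRUE)[[1]][pos]
      gc <- gc + sum(chars %in% c("G", "C"))
      total <- total + sum(chars %in% c("A", "C", "G", "T"))
    }
  }
  pooled <- if (total == 0) NA_real_ else gc / total
  if (is.na(pooled)) message("all important position sets are empty")
  structure(list(per_sequence = per, mean = pooled, n = length(seqs),
                 slice = NULL, n_positions = total),
            class = "gc_report")
}
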