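#' One-hot encode a DNA sequence
#'
#' Encodes a DNA string over `{A, C, G, T, N}` (case-insensitive) as an
#' `l x 4` matrix with channel order (A, C, G, T): A = (1,0,0,0),
#' C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1). `N` becomes an all-zero
#' row, which keeps the channel semantics and contributes nothing to
#' convolutions or saliency.
#'
#' @param sequence A single DNA string.
#' @return An `l x 4` numeric matrix with columns named A, C, G, T.
#' @export
#' @examples
#' one_hot_encode("ACGT")
one_hot_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  bad <- which(is.na(code) & chars != "N")
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d", chars[bad[1]], bad[1]))
  }
  m <- matrix(0, length(chars), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- which(!is.na(code))
  m[cbind(ok, code[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot_encode()]: the argmax channel per row, with all-zero
#' rows decoded as `N`.
#'
#' @param onehot An `l x 4` matrix in channel order (A, C, G, T).
#' @return A DNA string.
#' @export
decode_onehot <- function(onehot) {
  stopifnot(is.matrix(onehot), ncol(onehot) == 4)
  bases <- c("A", "C", "G", "T")
  out <- character(nrow(onehot))
  hit <- max.col(onehot, ties.method = "first")
  any_on <- rowSums(onehot) > 0
  out[any_on] <- bases[hit[any_on]]
  out[!any_on] <- "N"
  paste(out, collapse = "")
}

#' Build an encoded TSS-window dataset
#'
#' The central container: a set of equal-length DNA windows centred on
#' bidirectional-TSS midpoints, their one-hot encodings (stored as an
#' `l x 4 x n` array for batched model input), and promoter (1) / enhancer
#' (0) labels.
#'
#' @param sequences Character vector of equal-length DNA strings.
#' @param labels Numeric/integer vector of 0/1 labels (1 = promoter), or a
#'   character vector with values `"promoter"`/`"enhancer"`.
#' @param ids Sequence identifiers (default `seq_1` ...).
#' @param meta Optional data.frame of per-sequence metadata.
#' @return An object of class `tss_dataset` with fields `ids`, `sequences`,
#'   `labels`, `onehot`, `l`, `n`, `meta`.
#' @export
tss_dataset <- function(sequences, labels, ids = NULL, meta = NULL) {
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n == 0) stop("no sequences")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    stop(sprintf("sequences differ in length (%s)",
                 paste(unique(lens), collapse = ", ")))
  }
  l <- lens[1]
  if (is.character(labels)) {
    labels <- match.arg(labels, c("enhancer", "promoter"), several.ok = TRUE)
    labels <- as.integer(labels == "promoter")
  }
  labels <- as.integer(labels)
  stopifnot(length(labels) == n, all(labels %in% c(0L, 1L)))
  if (is.null(ids)) ids <- paste0("seq_", seq_len(n))
  onehot <- array(0, dim = c(l, 4, n))
  for (i in seq_len(n)) onehot[, , i] <- one_hot_encode(sequences[i])
  structure(list(ids = as.character(ids), sequences = sequences,
                 labels = labels, onehot = onehot, l = l, n = n, meta = meta),
            class = "tss_dataset")
}

#' @export
print.tss_dataset <- function(x, ...) {
  cat(sprintf("tss_dataset: %d sequences of length %d (%d promoter, %d enhancer)\n",
              x$n, x$l, sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' @export
length.tss_dataset <- function(x) x$n

#' Subset a TSS-window dataset
#' @param x A `tss_dataset`.
#' @param i Index vector.
#' @param ... Ignored.
#' @export
`[.tss_dataset` <- function(x, i, ...) {
  i <- seq_len(x$n)[i]
  structure(list(ids = x$ids[i], sequences = x$sequences[i],
                 labels = x$labels[i],
                 onehot = x$onehot[, , i, drop = FALSE], l = x$l,
                 n = length(i),
                 meta = if (!is.null(x$meta)) x$meta[i, , drop = FALSE]),
            class = "tss_dataset")
}

#' Read a labelled FASTA file into a dataset
#'
#' Reads equal-length windows from FASTA and attaches promoter/enhancer
#' labels given either as a named vector or as a two-column tab-separated
#' file (id, label; no header).
#'
#' @param fasta Path to a FASTA file of equal-length windows.
#' @param labels Named vector (names = record ids) or path to a two-column
#'   TSV mapping id to label (0/1 or enhancer/promoter).
#' @return A [tss_dataset()].
#' @export
read_labeled_fasta <- function(fasta, labels) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    tab <- read.table(labels, sep = "\t", header = FALSE,
                      col.names = c("id", "label"),
                      colClasses = c("character", "character"))
    labels <- stats::setNames(tab$label, tab$id)
  }
  if (is.null(names(labels))) stop("labels must be named by sequence id")
  missing <- setdiff(ids, names(labels))
  if (length(missing)) {
    stop("no label for sequence id(s): ", paste(missing, collapse = ", "))
  }
  lab <- labels[ids]
  if (all(lab %in% c("0", "1"))) lab <- as.integer(lab)
  tss_dataset(as.character(seqs), lab, ids = ids)
}

#' Extract fixed windows around bidirectional-TSS midpoints
#'
#' Takes BED intervals (0-based, half-open) marking TSS-pair midpoints --
#' the single base of a 1-bp record, or the centre of a wider record -- and
#' extracts the window `[midpoint - flank, midpoint + flank)` from the
#' genome, so a 250-bp flank yields 500-bp windows and a 300-bp flank
#' 600-bp windows. Windows overrunning a contig boundary are dropped with
#' a message.
#'
#' @param intervals Path to a BED file, or a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open) and optionally `name`.
#' @param genome A `DNAStringSet` or path to a FASTA file.
#' @param flank Flank size in bp on each side of the midpoint.
#' @return A list with `windows` (data.frame: chrom, start, end, midpoint,
#'   id) and `sequences` (a `DNAStringSet` of length-`2*flank` windows).
#' @export
extract_windows <- function(intervals, genome, flank) {
  stopifnot(flank > 0)
  if (is.character(intervals)) {
    gr <- rtracklayer::import(intervals, format = "BED")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    nm <- gr$name
    df$id <- if (!is.null(nm) && !all(is.na(nm))) nm else
      paste0("win_", seq_along(gr))
  } else {
    df <- as.data.frame(intervals)
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    if (is.null(df$id)) {
      df$id <- if (!is.null(df$name)) df$name else paste0("win_", seq_len(nrow(df)))
    }
  }
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  absent <- setdiff(unique(df$chrom), names(genome))
  if (length(absent)) {
    stop("contig(s) absent from genome: ", paste(absent, collapse = ", "))
  }
  midpoint <- df$start + (df$end - df$start) %/% 2L
  start <- midpoint - flank
  end <- midpoint + flank
  clen <- Biostrings::width(genome)[match(df$chrom, names(genome))]
  keep <- start >= 0 & end <= clen
  if (any(!keep)) {
    message(sum(!keep), " window(s) dropped at contig boundaries: ",
            paste(df$id[!keep], collapse = ", "))
  }
  windows <- data.frame(chrom = df$chrom, start = start, end = end,
                        midpoint = midpoint, id = df$id,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(vapply(which(keep), function(i) {
    as.character(Biostrings::subseq(genome[[df$chrom[i]]],
                                    start = start[i] + 1L, end = end[i]))
  }, ""))
  names(seqs) <- windows$id
  list(windows = windows, sequences = seqs)
}
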