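#' Specify a synthetic bidirectional-TSS dataset
#'
#' The generator emulates the sequence-level structure that separates
#' promoter-like (US: unstable-stable) from enhancer-like (UU:
#' unstable-unstable) bidirectional TSS windows: fixed-length windows
#' centred on the TSS-pair midpoint, class-dependent overall GC content
#' (defaults 63% vs 50%) and an elevated-GC downstream region at +20..+120
#' bp from the midpoint in the sense direction (defaults 67% vs 51%).
#' Every position is drawn independently; within the GC total, G and C are
#' equally likely, as are A and T. The flanking (non-downstream) GC level
#' is solved so that the whole-window expectation equals the global
#' parameter. Sense/antisense TSS positions (at +/- spacing/2) are carried
#' as metadata only. Optional motifs can be planted in a positional window
#' with a per-class probability.
#'
#' @param n_promoter,n_enhancer Sequences per class.
#' @param l Window length (500 or 600; must be divisible by 100).
#' @param promoter_gc_global,enhancer_gc_global Whole-window GC fractions.
#' @param promoter_gc_downstream,enhancer_gc_downstream GC fractions over
#'   the downstream window.
#' @param downstream_window Midpoint-relative half-open interval of the
#'   downstream region (default `c(20, 120)`).
#' @param tss_spacing_promoter,tss_spacing_enhancer Sense/antisense TSS
#'   spacing in bp (metadata; class means 120 and 91).
#' @param motifs Optional list of motif plants, each a list with elements
#'   `motif` (consensus string), `window` (`c(from, to)` relative,
#'   half-open), `class` (`"promoter"`, `"enhancer"` or `"both"`), and
#'   `prob` (per-sequence planting probability, default 1).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_promoter = 1000, n_enhancer = 1000, l = 500,
                           promoter_gc_global = 0.63,
                           enhancer_gc_global = 0.50,
                           promoter_gc_downstream = 0.67,
                           enhancer_gc_downstream = 0.51,
                           downstream_window = c(20, 120),
                           tss_spacing_promoter = 120,
                           tss_spacing_enhancer = 91,
                           motifs = NULL, seed = 1L) {
  stopifnot(n_promoter >= 1, n_enhancer >= 1, l %% 100 == 0,
            length(downstream_window) == 2,
            downstream_window[2] > downstream_window[1])
  for (p in c(promoter_gc_global, enhancer_gc_global,
              promoter_gc_downstream, enhancer_gc_downstream)) {
    if (p <= 0 || p >= 1) stop("GC parameters must lie in (0, 1)")
  }
  spec <- list(n_promoter = as.integer(n_promoter),
               n_enhancer = as.integer(n_enhancer), l = as.integer(l),
               promoter_gc_global = promoter_gc_global,
               enhancer_gc_global = enhancer_gc_global,
               promoter_gc_downstream = promoter_gc_downstream,
               enhancer_gc_downstream = enhancer_gc_downstream,
               downstream_window = as.integer(downstream_window),
               tss_spacing_promoter = tss_spacing_promoter,
               tss_spacing_enhancer = tss_spacing_enhancer,
               motifs = motifs, seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  # fail early on infeasible flank GC
  flank_gc(spec, "promoter")
  flank_gc(spec, "enhancer")
  spec
}

# GC level required of the non-downstream positions so the whole-window
# expectation matches the global parameter.
flank_gc <- function(spec, class) {
  gg <- if (class == "promoter") spec$promoter_gc_global else spec$enhancer_gc_global
  gd <- if (class == "promoter") spec$promoter_gc_downstream else spec$enhancer_gc_downstream
  w <- diff(spec$downstream_window)
  fg <- (spec$l * gg - w * gd) / (spec$l - w)
  if (fg <= 0 || fg >= 1) {
    stop(sprintf(
      "infeasible %s GC parameters: downstream %.3f over %d bp forces flank GC %.3f",
      class, gd, w, fg))
  }
  fg
}

# Draw an n x l base matrix: downstream columns at gc_down, the rest at the
# compensating flank level.
draw_class <- function(n, spec, class) {
  l <- spec$l
  gd <- if (class == "promoter") spec$promoter_gc_downstream else spec$enhancer_gc_downstream
  gf <- flank_gc(spec, class)
  down_idx <- rel_to_index(spec$downstream_window[1]:(spec$downstream_window[2] - 1), l)
  gc_by_col <- rep(gf, l)
  gc_by_col[down_idx] <- gd
  u <- matrix(runif(n * l), n, l)
  # cumulative cut points for (A, C, G, T) at GC fraction g:
  # A < (1-g)/2 < C < 1/2 + g/2... laid out as A, C, G, T with equal splits
  c1 <- matrix((1 - gc_by_col) / 2, n, l, byrow = TRUE)
  c2 <- c1 + matrix(gc_by_col / 2, n, l, byrow = TRUE)
  c3 <- c2 + matrix(gc_by_col / 2, n, l, byrow = TRUE)
  idx <- 1L + (u > c1) + (u > c2) + (u > c3)
  matrix(c("A", "C", "G", "T")[idx], n, l)
}

#' Plant a motif into a sequence window
#'
#' Writes the motif at a uniformly random offset inside a midpoint-relative
#' window, overwriting the background. An empty motif leaves the sequence
#' unchanged.
#'
#' @param sequence A single DNA string.
#' @param motif Consensus string to plant.
#' @param window `c(from, to)` midpoint-relative half-open interval the
#'   motif must fit inside.
#' @return The modified sequence, with the chosen midpoint-relative start
#'   in attribute `motif_start` (or `NA` for an empty motif).
#' @export
plant_motif <- function(sequence, motif, window) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            length(window) == 2)
  if (nchar(motif) == 0) {
    attr(sequence, "motif_start") <- NA_integer_
    return(sequence)
  }
  l <- nchar(sequence)
  starts <- window[1]:(window[2] - nchar(motif))
  if (window[2] - window[1] < nchar(motif)) {
    stop(sprintf("motif of length %d does not fit in window [%d, %d)",
                 nchar(motif), window[1], window[2]))
  }
  rel <- starts[sample.int(length(starts), 1)]
  at <- rel_to_index(rel, l)
  out <- paste0(substr(sequence, 1, at - 1), toupper(motif),
                substr(sequence, at + nchar(motif), l))
  attr(out, "motif_start") <- rel
  out
}

#' Generate a labelled synthetic bidirectional-TSS dataset
#'
#' Draws the promoter-class and enhancer-class windows specified by a
#' [synthetic_spec()], optionally plants motifs, and (optionally) writes
#' the dataset to disk as FASTA windows, a BED file of midpoints on a
#' synthetic contig `synth1` (windows tiled end to end), and a two-column
#' label TSV. Output is byte-identical for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir If non-NULL, write `sequences.fa`, `midpoints.bed` and
#'   `labels.tsv` here.
#' @return A [tss_dataset()] (promoters first) whose `meta` records the
#'   metadata TSS positions and any planted motif starts.
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  pro <- draw_class(spec$n_promoter, spec, "promoter")
  enh <- draw_class(spec$n_enhancer, spec, "enhancer")
  seqs <- c(apply(pro, 1, paste, collapse = ""),
            apply(enh, 1, paste, collapse = ""))
  labels <- c(rep(1L, spec$n_promoter), rep(0L, spec$n_enhancer))
  ids <- c(sprintf("pro_%04d", seq_len(spec$n_promoter)),
           sprintf("enh_%04d", seq_len(spec$n_enhancer)))
  spacing <- ifelse(labels == 1, spec$tss_spacing_promoter,
                    spec$tss_spacing_enhancer)
  meta <- data.frame(id = ids, label = labels,
                     tss_sense_rel = round(spacing / 2),
                     tss_antisense_rel = -round(spacing / 2),
                     stringsAsFactors = FALSE)
  for (m in spec$motifs %||% list()) {
    cls <- m$class %||% "both"
    prob <- m$prob %||% 1
    target <- switch(cls, promoter = labels == 1, enhancer = labels == 0,
                     both = rep(TRUE, length(labels)))
    col <- paste0("motif_", m$motif, "_start")
    meta[[col]] <- NA_integer_
    for (i in which(target)) {
      if (runif(1) <= prob) {
        planted <- plant_motif(seqs[i], m$motif, m$window)
        seqs[i] <- as.character(planted)
        meta[[col]][i] <- attr(planted, "motif_start")
      }
    }
  }
  data <- tss_dataset(seqs, labels, ids = ids, meta = meta)
  if (!is.null(out_dir)) write_dataset(data, out_dir)
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FASTA windows + BED midpoints (0-based half-open, windows tiled on a
# synthetic contig) + label TSV.
write_dataset <- function(data, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dss <- Biostrings::DNAStringSet(data$sequences)
  names(dss) <- data$ids
  Biostrings::writeXStringSet(dss, file.path(out_dir, "sequences.fa"))
  flank <- data$l / 2
  midpoint <- (seq_len(data$n) - 1) * data$l + flank
  bed <- data.frame(chrom = "synth1", start = midpoint, end = midpoint + 1,
                    name = data$ids, score = 0, strand = "+")
  write.table(bed, file.path(out_dir, "midpoints.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(id = data$ids, label = data$labels),
              file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(out_dir)
}
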