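#' Gradient saliency scores for promoter predictions
#'
#' First-order Taylor attribution: the model's class score around an input
#' `X` is locally `S(X) ~ w'X + b`, with `w` obtained by one step of
#' back-propagation to the input. The raw importance of position `i` is the
#' absolute gradient at the observed channel, `|dS/dx[i, c_i]|` (the
#' alternative `reduce = "max"` takes the largest absolute gradient over
#' the four channels). Dropout is disabled; by default the gradient is
#' taken on the pre-sigmoid score, which makes the scores invariant to a
#' shift of the output bias (`target = "probability"` rescales by
#' `p(1 - p)` instead).
#'
#' @param model A trained `tss_cnn`.
#' @param data A [tss_dataset()], array, matrix or character vector (as in
#'   [predict.tss_cnn()]).
#' @param reduce `"observed"` (gradient at the observed channel; positions
#'   whose row is all zero, i.e. `N`, score 0) or `"max"`.
#' @param target `"score"` (pre-sigmoid, default) or `"probability"`.
#' @param batch_size Sequences per backward pass.
#' @return An `n x l` matrix of non-negative raw scores (rownames = ids
#'   when available).
#' @export
compute_saliency <- function(model, data, reduce = c("observed", "max"),
                             target = c("score", "probability"),
                             batch_size = 128) {
  reduce <- match.arg(reduce)
  target <- match.arg(target)
  stopifnot(inherits(model, "tss_cnn"))
  ids <- if (inherits(data, "tss_dataset")) data$ids
  x <- as_input_array(data, model$arch$input_length)
  d <- arch_dims(model$arch)
  n <- dim(x)[3]
  l <- dim(x)[1]
  raw <- matrix(0, n, l)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    res <- cnn_core(x[, , idx, drop = FALSE], model$weights,
                    d$k1, d$p1, d$k2, d$p2, labels = NULL, dropout_p = 0,
                    input_grad = TRUE)
    g <- res$input_grad
    if (target == "probability") {
      scale <- res$prob * (1 - res$prob)
      for (j in seq_along(idx)) g[, , j] <- g[, , j] * scale[j]
    }
    for (j in seq_along(idx)) {
      raw[idx[j], ] <- if (reduce == "observed") {
        abs(rowSums(g[, , j] * x[, , idx[j]]))
      } else {
        apply(abs(g[, , j]), 1, max)
      }
    }
  }
  rownames(raw) <- ids
  raw
}

#' Normalize raw saliency scores to per-sequence importance scores
#'
#' Divides each score vector by its sum so every sequence's importance
#' scores sum to 1 and are comparable across sequences. A degenerate
#' all-zero vector (zero gradient everywhere) becomes uniform `1/l`,
#' reflecting that no position is more important than another.
#'
#' @param raw Non-negative score vector, or an `n x l` matrix of per-row
#'   score vectors.
#' @return Object of the same shape whose (row) sums are 1.
#' @export
#' @examples
#' normalize_scores(c(2, 0, 0))
normalize_scores <- function(raw) {
  if (is.matrix(raw)) return(t(apply(raw, 1, normalize_scores)))
  if (any(raw < 0)) stop("raw saliency scores must be non-negative")
  s <- sum(raw)
  if (s == 0) rep(1 / length(raw), length(raw)) else raw / s
}

#' Call important positions from normalized importance scores
#'
#' A position is important when its normalized importance score strictly
#' exceeds `1/l`, the score every position of a random sequence would
#' contribute equally: 0.002 for 500-bp windows and 1/600 (about 0.00167)
#' for 600-bp windows. Uniform scores therefore yield no important
#' positions.
#'
#' @param normalized Normalized score vector (sums to 1), or an `n x l`
#'   matrix.
#' @return Integer vector of 1-based positions, or a list of such vectors
#'   for matrix input.
#' @export
call_important_positions <- function(normalized) {
  if (is.matrix(normalized)) {
    return(lapply(seq_len(nrow(normalized)),
                  function(i) call_important_positions(normalized[i, ])))
  }
  which(normalized > 1 / length(normalized))
}

#' Saliency importance threshold for a window length
#' @param l Window length in bp.
#' @return `1/l`.
#' @export
#' @examples
#' saliency_threshold(500)  # 0.002
saliency_threshold <- function(l) 1 / l

#' Select the top-predicted promoter sequences
#'
#' Keeps sequences predicted promoter with probability above `prob_min`
#' (default 0.95), ordered by decreasing probability and truncated to
#' `top_n` (default 50) -- the selection used to build aggregate saliency
#' maps over confidently predicted promoters.
#'
#' @param model A trained `tss_cnn`.
#' @param data A [tss_dataset()].
#' @param prob_min Probability threshold.
#' @param top_n Maximum number of sequences kept.
#' @return A [tss_dataset()] subset with a `probabilities` attribute;
#'   empty (with a warning) if nothing qualifies.
#' @export
select_top_predictions <- function(model, data, prob_min = 0.95, top_n = 50) {
  stopifnot(top_n >= 1, inherits(data, "tss_dataset"))
  p <- predict(model, data)
  sel <- which(p > prob_min)
  if (length(sel) == 0) {
    warning(sprintf("no sequence predicted above %.3f", prob_min))
  } else if (length(sel) < top_n) {
    message(sprintf("only %d sequence(s) above %.3f", length(sel), prob_min))
  }
  sel <- sel[order(p[sel], decreasing = TRUE)]
  sel <- head(sel, top_n)
  out <- data[sel]
  attr(out, "probabilities") <- p[sel]
  out
}

#' Aggregate per-sequence importance scores into a positional map
#'
#' Stacks normalized score vectors into a matrix whose columns are
#' midpoint-relative positions `-l/2 .. l/2 - 1`, the coordinate frame in
#' which downstream slices such as +20..+120 are read off.
#'
#' @param normalized An `n x l` matrix of normalized scores (all rows sum
#'   to 1), or a single vector.
#' @return An object of class `saliency_map`: the score matrix with
#'   relative-position column names, plus `l` and the `1/l` threshold.
#' @export
aggregate_saliency <- function(normalized) {
  if (!is.matrix(normalized)) normalized <- matrix(normalized, nrow = 1)
  l <- ncol(normalized)
  if (any(abs(rowSums(normalized) - 1) > 1e-6)) {
    stop("rows must be normalized importance scores summing to 1")
  }
  colnames(normalized) <- relative_positions(l)
  structure(list(scores = normalized, l = l,
                 threshold = saliency_threshold(l)),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency_map: %d sequence(s) x %d positions (%+d..%+d), threshold %.5f\n",
              nrow(x$scores), x$l, -x$l / 2, x$l / 2 - 1, x$threshold))
  invisible(x)
}

#' Mean importance score over a midpoint-relative region
#'
#' @param map A [aggregate_saliency()] result.
#' @param from,to Half-open midpoint-relative interval `[from, to)`, e.g.
#'   `region_mean(map, 20, 120)` for the +20..+120 downstream region.
#' @param per_sequence If `TRUE`, return one mean per sequence instead of
#'   the grand mean.
#' @return Numeric scalar, or vector when `per_sequence = TRUE`.
#' @export
region_mean <- function(map, from, to, per_sequence = FALSE) {
  stopifnot(inherits(map, "saliency_map"), to > from)
  cols <- rel_to_index(from:(to - 1), map$l)
  m <- map$scores[, cols, drop = FALSE]
  if (per_sequence) rowMeans(m) else mean(m)
}
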