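#' Specify a constrained two-convolutional-layer architecture
#'
#' The model family: two stride-1, zero-padded ("same") convolutional
#' layers, each ReLU-activated and followed by max-pooling whose stride
#' equals its window, then a 512-unit ReLU hidden layer and a single
#' sigmoid output unit giving P(promoter). The two max-pool windows are
#' coupled so their product is 100; together with an input length divisible
#' by 100 this makes the flattened input to the hidden layer --
#' `(l / 100) * n_filters_2` values -- identical across every member of the
#' family, so pooling configurations can be compared without changing the
#' fully connected capacity.
#'
#' @param input_length Window length `l` in bp; must be divisible by 100.
#' @param n_filters_1 First-layer filter count (30 by default; 60/90/120 in
#'   the wider variants).
#' @param filter_size_1 First-layer filter size in bp (odd; 9/19/29).
#' @param pool_1 First max-pool window (one of 1, 2, 4, 10, 25, 50, 100).
#' @param n_filters_2 Second-layer filter count (128).
#' @param filter_size_2 Second-layer filter size (5).
#' @param pool_2 Second max-pool window; defaults to `100 / pool_1`.
#' @param hidden_units Fully connected hidden layer width (512).
#' @return An object of class `architecture_spec`.
#' @export
#' @examples
#' architecture_spec(500, pool_1 = 10, n_filters_1 = 90)
architecture_spec <- function(input_length = 500, n_filters_1 = 30,
                              filter_size_1 = 19, pool_1 = 10,
                              n_filters_2 = 128, filter_size_2 = 5,
                              pool_2 = 100 / pool_1, hidden_units = 512) {
  spec <- list(input_length = as.integer(input_length),
               n_filters_1 = as.integer(n_filters_1),
               filter_size_1 = as.integer(filter_size_1),
               pool_1 = as.integer(pool_1),
               n_filters_2 = as.integer(n_filters_2),
               filter_size_2 = as.integer(filter_size_2),
               pool_2 = as.integer(pool_2),
               hidden_units = as.integer(hidden_units))
  if (spec$pool_1 * spec$pool_2 != 100) {
    stop(sprintf("max-pool windows (%d, %d) do not multiply to 100",
                 spec$pool_1, spec$pool_2))
  }
  if (spec$input_length %% 100 != 0) {
    stop("input_length must be divisible by 100, got ", spec$input_length)
  }
  if (spec$filter_size_1 %% 2 == 0 || spec$filter_size_2 %% 2 == 0) {
    stop("filter sizes must be odd for symmetric zero padding")
  }
  if (spec$n_filters_1 < 1 || spec$n_filters_2 < 1 || spec$hidden_units < 1) {
    stop("filter and unit counts must be positive")
  }
  class(spec) <- "architecture_spec"
  spec
}

#' Size of the flattened input to the hidden layer
#'
#' `(l / 100) * n_filters_2`, invariant across all legal pool pairs.
#'
#' @param spec An [architecture_spec()].
#' @return Integer.
#' @export
hidden_input_size <- function(spec) {
  as.integer(spec$input_length / 100 * spec$n_filters_2)
}

#' Total trainable parameter count of an architecture
#' @param spec An [architecture_spec()].
#' @return Integer.
#' @export
n_parameters <- function(spec) {
  with(spec, filter_size_1 * 4L * n_filters_1 + n_filters_1 +
         filter_size_2 * n_filters_1 * n_filters_2 + n_filters_2 +
         hidden_input_size(spec) * hidden_units + hidden_units +
         hidden_units + 1L)
}

#' Model name in the CNN-p(f) convention
#'
#' `CNN-10` is the 30-filter model with first pool 10; widened variants are
#' written `CNN-10(90)`, and non-default first-layer filter sizes
#' `CNN_9-10(90)`.
#'
#' @param spec An [architecture_spec()].
#' @return Character name.
#' @export
model_name <- function(spec) {
  nm <- paste0("CNN-", spec$pool_1)
  if (spec$filter_size_1 != 19L) nm <- paste0("CNN_", spec$filter_size_1, "-", spec$pool_1)
  if (spec$n_filters_1 != 30L) nm <- paste0(nm, "(", spec$n_filters_1, ")")
  nm
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf(
    "%s: l=%d | conv1 %d x %d, pool %d | conv2 %d x %d, pool %d | hidden %d\n",
    model_name(x), x$input_length, x$n_filters_1, x$filter_size_1, x$pool_1,
    x$n_filters_2, x$filter_size_2, x$pool_2, x$hidden_units))
  invisible(x)
}

#' Specify the training regime
#'
#' Mini-batch gradient descent with the Adam optimizer on binary
#' cross-entropy: batches of 30 sequences for 40 epochs, dropout 0.5 after
#' each convolutional layer and the hidden layer, learning rate 3e-4 with a
#' per-update decay of 1e-6 (`lr_t = lr / (1 + decay * t)` at update step
#' `t`).
#'
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training data.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param learning_rate Adam base learning rate.
#' @param lr_decay Per-update multiplicative learning-rate decay.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; fixed seed gives bit-identical training runs.
#' @return An object of class `training_spec`.
#' @export
training_spec <- function(batch_size = 30, epochs = 40, dropout = 0.5,
                          learning_rate = 3e-4, lr_decay = 1e-6, seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, lr_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "training_spec")
}

#' The coupled max-pool sweep
#'
#' The seven pool pairs (1,100), (2,50), (4,25), (10,10), (25,4), (50,2),
#' (100,1) at 30 first-layer filters of size 19.
#'
#' @param input_length Window length `l`.
#' @return List of [architecture_spec()]s named CNN-1 ... CNN-100.
#' @export
pool_sweep_specs <- function(input_length = 500) {
  pools <- c(1, 2, 4, 10, 25, 50, 100)
  specs <- lapply(pools, function(p) {
    architecture_spec(input_length, pool_1 = p)
  })
  stats::setNames(specs, vapply(specs, model_name, ""))
}

#' The first-layer filter-count sweep
#'
#' 30, 60, 90 and 120 filters at pool pair (10, 10).
#'
#' @param input_length Window length `l`.
#' @return Named list of [architecture_spec()]s.
#' @export
filter_count_sweep_specs <- function(input_length = 500) {
  specs <- lapply(c(30, 60, 90, 120), function(f) {
    architecture_spec(input_length, n_filters_1 = f, pool_1 = 10)
  })
  stats::setNames(specs, vapply(specs, model_name, ""))
}

#' The first-layer filter-size sweep
#'
#' Filter sizes 9, 19 and 29 at 90 filters and pool pair (10, 10).
#'
#' @param input_length Window length `l`.
#' @return Named list of [architecture_spec()]s.
#' @export
filter_size_sweep_specs <- function(input_length = 500) {
  specs <- lapply(c(9, 19, 29), function(s) {
    architecture_spec(input_length, n_filters_1 = 90, filter_size_1 = s,
                      pool_1 = 10)
  })
  stats::setNames(specs, vapply(specs, model_name, ""))
}
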