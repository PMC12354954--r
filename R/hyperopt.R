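# Random-search hyperparameter optimization with the two-phase protocol:
# fast screening (5-fold, 15 epochs) of uniformly sampled configurations,
# then fine 10-fold / 30-epoch cross-validation of the winner.

#' Define the random-search space
#'
#' Defaults are the six candidate lists searched in this method: grid
#' sides 6/7/8, kernels 3/4/5, strides 1/2/3, 1-3 dense layers of
#' 4/8/16/32 units, ReLU or SeLU — 648 combinations in total, of which
#' \code{n_iter} are sampled.
#'
#' @param reshape_dim,conv_kernel,conv_stride,dense_layers,dense_units,activation
#'   Candidate vectors (all nonempty).
#' @param n_iter Number of random draws (default 30, about 5\% of the
#'   full space).
#' @param seed Master seed for sampling.
#' @return A \code{"search_space"} list.
#' @export
search_space <- function(reshape_dim = c(6L, 7L, 8L),
                         conv_kernel = c(3L, 4L, 5L),
                         conv_stride = c(1L, 2L, 3L),
                         dense_layers = c(1L, 2L, 3L),
                         dense_units = c(4L, 8L, 16L, 32L),
                         activation = c("relu", "selu"),
                         n_iter = 30L, seed = 1L) {
  lists <- list(reshape_dim = reshape_dim, conv_kernel = conv_kernel,
                conv_stride = conv_stride, dense_layers = dense_layers,
                dense_units = dense_units, activation = activation)
  if (any(lengths(lists) == 0)) {
    stop("every candidate list must be nonempty", call. = FALSE)
  }
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  structure(c(lists, list(n_iter = as.integer(n_iter),
                          seed = as.integer(seed))),
            class = "search_space")
}

# Seed for one draw; distinct from fold seeds, within 32-bit range.
draw_seed <- function(seed, draw_index) {
  as.integer((as.numeric(seed) * 7919 + draw_index * 104729) %% 2147483647)
}

#' Sample one configuration from the search space
#'
#' Each field is drawn uniformly and independently from its candidate
#' list; the draw is a deterministic function of (space seed,
#' \code{draw_index}). Combinations that cannot form a network for the
#' given input (kernel larger than grid; zero-pad grid smaller than the
#' feature dimension) are rejected and redrawn; the number of rejections
#' is attached as attribute \code{"rejections"}.
#'
#' @param space A \code{\link{search_space}}.
#' @param draw_index 1-based index of the draw.
#' @param input_dim Feature dimension used to judge legality.
#' @param mode Input mapping mode (legality depends on it in zero_pad).
#' @return A \code{\link{hyperparams}} object.
#' @export
sample_config <- function(space, draw_index, input_dim = 40L,
                          mode = "dense_projection") {
  stopifnot(inherits(space, "search_space"))
  set.seed(draw_seed(space$seed, draw_index))
  pick <- function(v) v[[sample.int(length(v), 1L)]]
  rejections <- 0L
  repeat {
    hp <- try(hyperparams(pick(space$reshape_dim), pick(space$conv_kernel),
                          pick(space$conv_stride), pick(space$dense_layers),
                          pick(space$dense_units), pick(space$activation)),
              silent = TRUE)
    ok <- !inherits(hp, "try-error") &&
      !inherits(try(build_model(hp, input_dim, mode = mode, quiet = TRUE),
                    silent = TRUE), "try-error")
    if (ok) break
    rejections <- rejections + 1L
    if (rejections > 1000L) {
      stop("no legal configuration found in the search space for ",
           "input_dim = ", input_dim, ", mode = ", mode, call. = FALSE)
    }
  }
  attr(hp, "rejections") <- rejections
  hp
}

#' Screen one configuration with fast cross-validation
#'
#' The screening phase: stratified 5-fold CV at 15 epochs, reporting the
#' dual metrics mean ACC and mean MCC across validation folds. Folds are
#' a function of (labels, k, seed) only, so every configuration screened
#' with the same seed sees the same folds.
#'
#' @param hp A \code{\link{hyperparams}} object.
#' @param X,y Features and binary labels.
#' @param seed Seed shared across configurations for fair comparison.
#' @param k,epochs Screening folds and epochs (defaults 5 and 15).
#' @param filters,mode Passed to \code{\link{build_model}}.
#' @return Named numeric vector \code{c(ACC = ..., MCC = ...)}.
#' @export
screen_config <- function(hp, X, y, seed = 1L, k = 5L, epochs = 15L,
                          filters = 16L, mode = "dense_projection") {
  res <- cross_validate(X, y, hp, k = k, epochs = epochs, seed = seed,
                        filters = filters, mode = mode)
  c(ACC = res$means$ACC, MCC = res$means$MCC)
}

#' Random search over the hyperparameter space
#'
#' Draws \code{space$n_iter} configurations, screens each with 5-fold /
#' 15-epoch CV, and selects the winner by highest screening ACC (ties
#' broken by higher MCC, remaining ties by earliest draw). The winner is
#' then finely evaluated with 10-fold / 30-epoch cross-validation and
#' that result attached. Fully reproducible from (space, data, seed).
#'
#' @param space A \code{\link{search_space}}.
#' @param X,y Features and binary labels.
#' @param seed Seed for screening and final CV (fold assignment and
#'   training); sampling uses the space's own seed.
#' @param filters,mode Passed to \code{\link{build_model}}.
#' @param final_k,final_epochs Fine-validation folds and epochs
#'   (defaults 10 and 30).
#' @param verbose Print one line per draw.
#' @return A \code{"search_trace"}: data.frame \code{trace} (draw,
#'   sampled fields, screening ACC/MCC, rejections), \code{best_index},
#'   \code{best_hp}, and \code{best_cv} (the fine \code{cv_result}).
#' @export
random_search <- function(space, X, y, seed = 1L, filters = 16L,
                          mode = "dense_projection", final_k = 10L,
                          final_epochs = 30L, verbose = FALSE) {
  stopifnot(inherits(space, "search_space"))
  X <- as.matrix(X)
  rows <- vector("list", space$n_iter)
  hps <- vector("list", space$n_iter)
  for (d in seq_len(space$n_iter)) {
    hp <- sample_config(space, d, input_dim = ncol(X), mode = mode)
    sc <- screen_config(hp, X, y, seed = seed, filters = filters,
                        mode = mode)
    hps[[d]] <- hp
    rows[[d]] <- data.frame(
      draw = d, reshape_dim = hp$reshape_dim, conv_kernel = hp$conv_kernel,
      conv_stride = hp$conv_stride, dense_layers = hp$dense_layers,
      dense_units = hp$dense_units, activation = hp$activation,
      ACC = sc[["ACC"]], MCC = sc[["MCC"]],
      rejections = attr(hp, "rejections"))
    if (verbose) {
      message(sprintf("draw %2d: ACC %.4f MCC %.4f (%d/%d/%d %d x %d %s)",
                      d, sc[["ACC"]], sc[["MCC"]], hp$reshape_dim,
                      hp$conv_kernel, hp$conv_stride, hp$dense_layers,
                      hp$dense_units, hp$activation))
    }
  }
  trace <- do.call(rbind, rows)
  best <- order(-trace$ACC, -trace$MCC, trace$draw)[1]
  best_cv <- cross_validate(X, y, hps[[best]], k = final_k,
                            epochs = final_epochs, seed = seed,
                            filters = filters, mode = mode)
  structure(list(trace = trace, best_index = best, best_hp = hps[[best]],
                 best_cv = best_cv, seed = as.integer(seed),
                 space = space, filters = as.integer(filters), mode = mode),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  b <- x$trace[x$best_index, ]
  cat(sprintf(paste0("random search: %d draws; best draw %d ",
                     "(grid %d, kernel %d, stride %d, %d x %d, %s): ",
                     "screening ACC %.4f MCC %.4f\n"),
              nrow(x$trace), b$draw, b$reshape_dim, b$conv_kernel,
              b$conv_stride, b$dense_layers, b$dense_units, b$activation,
              b$ACC, b$MCC))
  cat("final ")
  print(x$best_cv)
  invisible(x)
}

#' Write a search trace to JSON and a TSV leaderboard
#'
#' @param st A \code{"search_trace"}.
#' @param json_path,tsv_path Output paths (either may be NULL to skip).
#'   The TSV leaderboard is sorted by the selection rule (ACC, then MCC,
#'   then draw).
#' @return \code{st}, invisibly.
#' @export
write_search_trace <- function(st, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(st, "search_trace"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(seed = st$seed, n_iter = st$space$n_iter,
           space_seed = st$space$seed, mode = st$mode,
           filters = st$filters, trace = st$trace,
           best_index = st$best_index, best_hp = unclass(st$best_hp),
           best_cv_means = st$best_cv$means),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    lb <- st$trace[order(-st$trace$ACC, -st$trace$MCC, st$trace$draw), ]
    utils::write.table(lb, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(st)
}
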