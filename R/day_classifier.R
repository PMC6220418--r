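#' Assemble a labelled training set of spikelet crops
#'
#' Pools annotated crops from a collection of scenes, then samples the
#' requested number per class without replacement. The canonical corpus
#' keeps the 10:2:1 background:closed:open proportion (5,000 / 1,000 / 500
#' crops with a disjoint 500/50/50 validation split); desk-scale corpora
#' use the same proportions at smaller counts. Crops are rescaled to
#' `out_size` x `out_size` RGB, conceptually the classic
#' `(34, 34, 3, N)` training array plus a parallel label vector.
#'
#' @param scenes List of scenes, each a list with elements `frame` (a
#'   [taa_frame()] or pixel array) and `annotations` (see
#'   [parse_annotations()]).
#' @param target_counts Named integer vector over
#'   `background`/`closed`/`open`; classes with 0 may be omitted.
#' @param validation_counts Optional named vector requesting a held-out
#'   validation split, sampled without replacement and disjoint from the
#'   training crops.
#' @param out_size Crop edge length (default 34).
#' @param seed Seed controlling the sampling.
#' @return A `taa_training_set`: list with `crops`, `labels`,
#'   `class_counts`, and optionally `validation` (itself a
#'   `taa_training_set`).
#' @export
build_training_set <- function(scenes,
                               target_counts = c(background = 5000,
                                                 closed = 1000, open = 500),
                               validation_counts = NULL, out_size = 34,
                               seed = NULL) {
  full <- setNames(rep(0L, 3), SPIKELET_LABELS)
  full[names(target_counts)] <- target_counts
  target_counts <- full
  pool <- list()
  pool_labels <- character(0)
  for (sc in scenes) {
    cr <- extract_crops(sc$frame, sc$annotations, out_size = out_size)
    pool <- c(pool, cr$crops)
    pool_labels <- c(pool_labels, cr$labels)
  }
  need <- target_counts
  if (!is.null(validation_counts)) {
    vfull <- setNames(rep(0L, 3), SPIKELET_LABELS)
    vfull[names(validation_counts)] <- validation_counts
    validation_counts <- vfull
    need <- need + validation_counts
  }
  avail <- table(factor(pool_labels, levels = SPIKELET_LABELS))
  short <- need - as.integer(avail)
  if (any(short > 0)) {
    cls <- names(need)[short > 0][1]
    stop(sprintf("not enough '%s' crops: need %d, have %d (deficit %d)",
                 cls, need[cls], avail[cls], short[cls]))
  }
  with_seed(seed, {
    take <- function(counts, exclude = integer(0)) {
      idx <- unlist(lapply(SPIKELET_LABELS, function(cl) {
        cand <- setdiff(which(pool_labels == cl), exclude)
        if (counts[cl] > 0) sample(cand, counts[cl]) else integer(0)
      }))
      idx
    }
    tr_idx <- take(target_counts)
    ts <- new_training_set(pool[tr_idx], pool_labels[tr_idx], out_size)
    if (!is.null(validation_counts)) {
      va_idx <- take(validation_counts, exclude = tr_idx)
      ts$validation <- new_training_set(pool[va_idx], pool_labels[va_idx],
                                        out_size)
    }
    ts
  })
}

new_training_set <- function(crops, labels, out_size) {
  structure(list(crops = crops, labels = labels,
                 class_counts = table(factor(labels, levels = SPIKELET_LABELS)),
                 out_size = out_size),
            class = "taa_training_set")
}

#' @export
print.taa_training_set <- function(x, ...) {
  cat(sprintf("<taa_training_set> %d crops (%d x %d): %s\n", length(x$crops),
              x$out_size, x$out_size,
              paste(names(x$class_counts), as.integer(x$class_counts),
                    sep = "=", collapse = ", ")))
  if (!is.null(x$validation))
    cat(sprintf("  + validation: %d crops\n", length(x$validation$crops)))
  invisible(x)
}

# Flatten crops into the feature matrix a backend consumes: each RGB crop
# is bilinearly downsampled to feature_size x feature_size per channel and
# scaled to [0, 1].
crop_features <- function(crops, feature_size) {
  t(vapply(crops, function(cr) {
    if (!is_rgb(cr)) stop("classifier crops must be RGB (rows x cols x 3)")
    as.vector(rescale_pixels(cr, feature_size, feature_size)) / 255
  }, numeric(feature_size * feature_size * 3L)))
}

#' Default classifier training configuration
#'
#' `rounds` caps optimiser iterations (the canonical 250), `learning_rate`
#' and `momentum` are carried for backends with SGD-style optimisers (the
#' bundled backends optimise by BFGS, where they do not apply), `decay` is
#' the L2 penalty, `feature_size` the per-side downsampling of crops into
#' pixel features (default 17, a clean 2x reduction of the 34-px crop),
#' and `hidden` the hidden-layer width of the `"nnet"` backend.
#'
#' @param rounds,learning_rate,momentum,decay,feature_size,hidden See above.
#' @return A named list.
#' @export
classifier_config <- function(rounds = 250, learning_rate = 1e-4,
                              momentum = 0.9, decay = 1e-4, feature_size = 17,
                              hidden = 8) {
  list(rounds = rounds, learning_rate = learning_rate, momentum = momentum,
       decay = decay, feature_size = feature_size, hidden = hidden)
}

#' Train a three-class spikelet tile classifier
#'
#' The classifier is a pluggable contract: any backend mapping a 34x34x3
#' crop to a `(background, closed, open)` probability triple summing to 1.
#' Two desk-scale reference backends are bundled: `"multinom"`
#' (multinomial logistic regression on downsampled pixel features, the
#' fast default) and `"nnet"` (a single-hidden-layer network on the same
#' features). Training is reproducible given `seed`.
#'
#' @param train A `taa_training_set` with at least two classes present.
#' @param backend `"multinom"` or `"nnet"`.
#' @param config See [classifier_config()].
#' @param seed Seed for backend initialisation.
#' @return A `taa_classifier` with the fitted backend, class order
#'   (`background`, `closed`, `open`), config and final training accuracy.
#' @export
train_classifier <- function(train, backend = c("multinom", "nnet"),
                             config = classifier_config(), seed = 1) {
  backend <- match.arg(backend)
  stopifnot(inherits(train, "taa_training_set"))
  if (!length(train$crops)) stop("empty training set")
  present <- unique(train$labels)
  if (length(present) < 2)
    stop("training set has a single class ('", present,
         "'); cannot fit a discriminator")
  x <- crop_features(train$crops, config$feature_size)
  y <- factor(train$labels, levels = SPIKELET_LABELS)
  y <- droplevels(y)
  fit <- with_seed(seed, switch(backend,
    multinom = nnet::multinom(y ~ ., data = data.frame(y = y, x),
                              maxit = config$rounds, decay = config$decay,
                              MaxNWts = 1e6, trace = FALSE),
    nnet = nnet::nnet(x, nnet::class.ind(y), size = config$hidden,
                      softmax = TRUE, maxit = config$rounds,
                      decay = config$decay, MaxNWts = 1e6, trace = FALSE)))
  model <- structure(list(backend = backend, config = config, fit = fit,
                          classes = SPIKELET_LABELS,
                          fitted_levels = levels(y), seed = seed,
                          version = 1L),
                     class = "taa_classifier")
  pred <- predict(model, train$crops)
  model$training_accuracy <- mean(colnames(pred)[max.col(pred)] == train$labels)
  model
}

#' Predict class probabilities for spikelet crops
#'
#' @param object A `taa_classifier`.
#' @param newdata A list of RGB crop arrays (or a single crop).
#' @param ... Unused.
#' @return A numeric matrix, one row per crop, columns `background`,
#'   `closed`, `open`; each row sums to 1.
#' @export
predict.taa_classifier <- function(object, newdata, ...) {
  if (!is.list(newdata)) newdata <- list(newdata)
  x <- crop_features(newdata, object$config$feature_size)
  raw <- switch(object$backend,
    multinom = {
      p <- predict(object$fit, newdata = data.frame(x), type = "probs")
      if (is.null(dim(p))) {
        if (length(object$fitted_levels) == 2L)
          p <- cbind(1 - p, p)           # binomial fit returns P(second level)
        else p <- matrix(p, nrow = 1)
      }
      p <- as.matrix(p)
      colnames(p) <- object$fitted_levels
      p
    },
    nnet = {
      p <- predict(object$fit, x)
      colnames(p) <- object$fitted_levels
      p
    })
  out <- matrix(0, nrow(x), 3, dimnames = list(NULL, object$classes))
  out[, colnames(raw)] <- raw
  out / rowSums(out)
}

#' @export
print.taa_classifier <- function(x, ...) {
  cat(sprintf("<taa_classifier> backend '%s', classes (%s)\n", x$backend,
              paste(x$classes, collapse = ", ")))
  if (!is.null(x$training_accuracy))
    cat(sprintf("  training accuracy %.1f%%\n", 100 * x$training_accuracy))
  invisible(x)
}

#' Serialise / restore a trained classifier
#'
#' Models are written as a single-file archive (RDS) holding a versioned
#' header, the training config and the fitted parameters.
#'
#' @param model A `taa_classifier`.
#' @param path File path.
#' @return `save_classifier` the path, `load_classifier` the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "taa_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "taa_classifier") || is.null(model$version))
    stop("not a taatrack classifier archive: ", path)
  model
}

#' Classify a daytime panicle image tile by tile
#'
#' The frame is resized to tile multiples, cut into `tile_size` tiles, and
#' every tile is scored by the classifier; each tile's call is the class
#' with the highest probability.
#'
#' @param model A `taa_classifier`.
#' @param image A daytime RGB [taa_frame()] or pixel array.
#' @param tile_size Tile edge (default 34).
#' @return A `taa_tile_calls` object: per-tile `labels` and probability
#'   matrix `probs`, class `counts`, plus the tiling geometry needed to
#'   map tiles back to original pixel coordinates.
#' @export
classify_image <- function(model, image, tile_size = 34) {
  px <- if (inherits(image, "taa_frame")) image$pixels else image
  if (!is_rgb(px))
    stop("classify_image() needs a daytime RGB frame; night (single-channel) ",
         "frames are handled by the motion detector (call_night_openings)")
  orig_dim <- dim(px)[1:2]
  resized <- resize_to_tile_multiple(px, tile_size)
  grid <- tile_image(resized, tile_size)
  probs <- predict(model, grid$tiles)
  labels <- colnames(probs)[max.col(probs, ties.method = "first")]
  counts <- table(factor(labels, levels = SPIKELET_LABELS))
  structure(list(labels = labels, probs = probs, counts = counts,
                 n_rows = grid$n_rows, n_cols = grid$n_cols,
                 tile_size = tile_size, origin_map = grid$origin_map,
                 resized_dim = dim(resized)[1:2], orig_dim = orig_dim),
            class = "taa_tile_calls")
}

#' @export
print.taa_tile_calls <- function(x, ...) {
  cat(sprintf("<taa_tile_calls> %d x %d tiles: %s\n", x$n_rows, x$n_cols,
              paste(names(x$counts), as.integer(x$counts), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.taa_tile_calls <- function(x, ...) {
  data.frame(tile_row = x$origin_map[, 1] / x$tile_size,
             tile_col = x$origin_map[, 2] / x$tile_size,
             label = x$labels,
             p_background = x$probs[, "background"],
             p_closed = x$probs[, "closed"],
             p_open = x$probs[, "open"])
}

# Bounding boxes (0-based half-open, in ORIGINAL image coordinates) of
# tiles carrying a given call.
tile_bboxes <- function(calls, label = "closed") {
  stopifnot(inherits(calls, "taa_tile_calls"))
  idx <- which(calls$labels == label)
  sr <- calls$orig_dim[1] / calls$resized_dim[1]
  sc <- calls$orig_dim[2] / calls$resized_dim[2]
  do.call(rbind, lapply(idx, function(i) {
    r0 <- calls$origin_map[i, 1]; c0 <- calls$origin_map[i, 2]
    data.frame(label = label,
               row_min = floor(r0 * sr), col_min = floor(c0 * sc),
               row_max = ceiling((r0 + calls$tile_size) * sr),
               col_max = ceiling((c0 + calls$tile_size) * sc))
  })) %||% empty_annotations()
}

#' Open-spikelet ratio of a classified image
#'
#' Fraction `n_open / (n_open + n_closed)`; background tiles are excluded
#' from the denominator.
#'
#' @param calls A `taa_tile_calls`.
#' @return A fraction in `[0, 1]`.
#' @export
open_ratio <- function(calls) {
  n_open <- as.integer(calls$counts["open"])
  n_closed <- as.integer(calls$counts["closed"])
  if (n_open + n_closed == 0)
    stop("no spikelet (open/closed) tiles: open ratio undefined")
  n_open / (n_open + n_closed)
}

#' Evaluate a classifier on a labelled validation set
#'
#' Overall accuracy is computed over all three classes; open-vs-closed
#' accuracy only over crops whose true label is open or closed, with a
#' background prediction on such a crop counted as an error.
#'
#' @param model A `taa_classifier`.
#' @param validation A `taa_training_set` of labelled crops.
#' @return List with `overall_accuracy`, `open_vs_closed_accuracy` and the
#'   `confusion` table (rows = truth, columns = prediction).
#' @export
evaluate_classifier <- function(model, validation) {
  stopifnot(inherits(validation, "taa_training_set"))
  if (!length(validation$crops)) stop("empty validation set")
  probs <- predict(model, validation$crops)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  truth <- validation$labels
  conf <- table(truth = factor(truth, levels = SPIKELET_LABELS),
                prediction = factor(pred, levels = SPIKELET_LABELS))
  oc <- truth %in% c("closed", "open")
  list(overall_accuracy = mean(pred == truth),
       open_vs_closed_accuracy = if (any(oc)) mean(pred[oc] == truth[oc])
                                 else NA_real_,
       confusion = conf)
}
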