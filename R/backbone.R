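#' Model architecture configuration
#'
#' The network has three stages.  A shared extractor `f` maps every input
#' feature vector to a common space where domain-invariant structure is
#' learned; `n_sources` unshared subnetworks `F_n` then map the common
#' features into per-source specific spaces (one per source-target pair);
#' and `n_sources` classifier heads `O_n` turn the specific features of
#' subnet `n` into class probabilities, `G_n = O_n o F_n`.  All stages are
#' dense: the extractor and subnets are affine + ReLU layers, the heads are
#' affine + softmax.
#'
#' @param input_dim Length of the input feature vector (1,647 for 61
#'   channels x 27 band points).
#' @param n_sources Number of source domains N (one subnet and head each).
#' @param n_classes Number of classes C (default 2: awake/fatigue).
#' @param common_dim Width of the shared feature space (default 64).
#' @param specific_dim Width of each domain-specific space (default 64).
#' @param input_layout Optional `c(channels, points_per_channel)`; when
#'   given, their product must equal `input_dim`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_dim, n_sources, n_classes = 2,
                         common_dim = 64, specific_dim = 64,
                         input_layout = NULL) {
  input_dim <- check_count(input_dim, "input_dim")
  n_sources <- check_count(n_sources, "n_sources", min = 2L)
  if (!is.null(input_layout)) {
    if (length(input_layout) != 2L ||
        prod(input_layout) != input_dim) {
      stopf("input_layout must be c(channels, points) with product %d",
            input_dim)
    }
  }
  structure(list(input_dim = input_dim, n_sources = n_sources,
                 n_classes = check_count(n_classes, "n_classes", min = 2L),
                 common_dim = check_count(common_dim, "common_dim"),
                 specific_dim = check_count(specific_dim, "specific_dim"),
                 input_layout = input_layout),
            class = "model_config")
}

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}

#' Initialise model parameters
#'
#' @param config A [model_config()].
#' @param seed Integer seed; equal seeds give bit-identical parameters.
#' @return An object of class `msda_model` holding the shared extractor
#'   weights (`W1`, `b1`), per-source subnet weights (`V[[n]]`, `cb[[n]]`)
#'   and head weights (`U[[n]]`, `d[[n]]`), plus the training step counter.
#' @export
init_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "model_config"))
  with_seed(seed, {
    model <- list(
      config = config,
      seed = as.integer(seed),
      step = 0L,
      W1 = he_init(config$common_dim, config$input_dim),
      b1 = numeric(config$common_dim),
      V = lapply(seq_len(config$n_sources), function(n)
        he_init(config$specific_dim, config$common_dim)),
      cb = lapply(seq_len(config$n_sources), function(n)
        numeric(config$specific_dim)),
      U = lapply(seq_len(config$n_sources), function(n)
        he_init(config$n_classes, config$specific_dim)),
      d = lapply(seq_len(config$n_sources), function(n)
        numeric(config$n_classes)),
      feature_center = NULL, feature_scale = NULL
    )
  })
  structure(model, class = "msda_model")
}

#' @export
print.msda_model <- function(x, ...) {
  cat(sprintf(paste0("<msda_model> %d-dim input -> %d common -> %d specific,",
                     " %d sources, %d classes (step %d)\n"),
              x$config$input_dim, x$config$common_dim, x$config$specific_dim,
              x$config$n_sources, x$config$n_classes, x$step))
  invisible(x)
}

check_batch <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$config$input_dim) {
    stopf("batch has %d features, model expects %d",
          ncol(x), model$config$input_dim)
  }
  x
}

check_source_index <- function(model, n) {
  n <- check_count(n, "n")
  if (n > model$config$n_sources) {
    stopf("source index %d out of range 1..%d", n, model$config$n_sources)
  }
  n
}

# standardization learned from the sources at training time
standardize_batch <- function(model, x) {
  if (is.null(model$feature_center)) return(x)
  sweep(sweep(x, 2L, model$feature_center), 2L, model$feature_scale, `/`)
}

#' Shared (domain-invariant) features
#'
#' @param model An [init_model()] state.
#' @param x Batch x input_dim matrix (raw feature scale; the model applies
#'   its stored standardization if it has been trained).
#' @return Batch x common_dim matrix.
#' @export
common_features <- function(model, x) {
  stopifnot(inherits(model, "msda_model"))
  x <- standardize_batch(model, check_batch(model, x))
  relu(sweep(x %*% t(model$W1), 2L, model$b1, `+`))
}

#' Domain-specific features from subnet n
#'
#' @param model An [init_model()] state.
#' @param common Batch x common_dim matrix from [common_features()].
#' @param n Source index in 1..N; subnets share no weights.
#' @return Batch x specific_dim matrix.
#' @export
specific_features <- function(model, common, n) {
  stopifnot(inherits(model, "msda_model"))
  n <- check_source_index(model, n)
  if (ncol(common) != model$config$common_dim) {
    stopf("`common` has %d columns, expected %d",
          ncol(common), model$config$common_dim)
  }
  relu(sweep(common %*% t(model$V[[n]]), 2L, model$cb[[n]], `+`))
}

#' Class probabilities from head n
#'
#' @param model An [init_model()] state.
#' @param specific Batch x specific_dim matrix from [specific_features()].
#' @param n Source index in 1..N.
#' @return Batch x n_classes matrix; every row is a probability
#'   distribution.
#' @export
classify <- function(model, specific, n) {
  stopifnot(inherits(model, "msda_model"))
  n <- check_source_index(model, n)
  if (ncol(specific) != model$config$specific_dim) {
    stopf("`specific` has %d columns, expected %d",
          ncol(specific), model$config$specific_dim)
  }
  softmax_rows(sweep(specific %*% t(model$U[[n]]), 2L, model$d[[n]], `+`))
}

# full forward pass through branch n with intermediate activations kept
# for backpropagation (x must already be standardized)
forward_branch <- function(model, x, n) {
  z1 <- sweep(x %*% t(model$W1), 2L, model$b1, `+`)
  h <- relu(z1)
  z2 <- sweep(h %*% t(model$V[[n]]), 2L, model$cb[[n]], `+`)
  s <- relu(z2)
  p <- softmax_rows(sweep(s %*% t(model$U[[n]]), 2L, model$d[[n]], `+`))
  list(x = x, z1 = z1, h = h, z2 = z2, s = s, p = p)
}

#' Save / load a model state
#'
#' The on-disk file round-trips bit-exactly: reloading and predicting gives
#' identical output.
#'
#' @param model An `msda_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "msda_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "msda_model"))
  model
}
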