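# YAML configuration for the command-line workflow. The YAML mirrors the
# experiment_config() structure; absent fields fall back to the defaults.

#' Read an experiment configuration from YAML
#'
#' Recognised top-level keys: `seed`, `n_volumes`, `split_fracs`, `theta`,
#' `k`, `scheme` (kind/sigma), and the nested sections `phantom`
#' (arguments of [phantom_params()]), `model` ([model_spec()]),
#' `init_train` and `finetune_train` ([train_config()]). Missing keys keep
#' their package defaults.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("seed", "n_volumes", "split_fracs", "theta", "k")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$phantom)) {
    p <- y$phantom
    if (!is.null(p$shape)) p$shape <- as.integer(unlist(p$shape))
    args$phantom <- do.call(phantom_params, p)
  }
  if (!is.null(y$model)) args$model <- do.call(model_spec, y$model)
  if (!is.null(y$init_train)) {
    args$init_train <- do.call(train_config, y$init_train)
  }
  if (!is.null(y$finetune_train)) {
    args$finetune_train <- do.call(train_config, y$finetune_train)
  }
  if (!is.null(y$scheme)) args$scheme <- do.call(weight_scheme, y$scheme)
  do.call(experiment_config, args)
}

#' Write an experiment configuration to YAML
#'
#' @param config An [experiment_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  y <- list(
    seed = config$seed, n_volumes = config$n_volumes,
    split_fracs = config$split_fracs,
    theta = config$theta, k = config$k,
    scheme = list(kind = config$scheme$kind, sigma = config$scheme$sigma),
    phantom = unclass(config$phantom),
    model = unclass(config$model),
    init_train = unclass(config$init_train),
    finetune_train = unclass(config$finetune_train))
  yaml::write_yaml(y, path)
  invisible(path)
}
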