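# Run configuration: one nested key/value structure covering every knob of
# the pipeline, read from YAML.  Unknown keys are rejected so typos cannot
# silently fall back to defaults; a seed is mandatory.

#' Default run configuration
#'
#' Returns the full nested configuration with every knob at its default.
#' Sections: `encoder` (window, filters, alphabet), `align` (temperature,
#' gap penalties, mode), `mrf` (mask rate, regularization), `train`
#' (phase step counts, learning rates, batch size), `eval` (minimum
#' separation, consistency gap penalties) and `simulate` (synthetic-family
#' shape).  `seed` is top-level and mandatory in every run.
#'
#' @param seed Integer seed.
#' @return A nested list of class `smurf_config`.
#' @export
default_config <- function(seed = 0L) {
  structure(list(
    seed = as.integer(seed),
    encoder = list(window_half_width = 9L, filters = 512L,
                   alphabet = "protein"),
    align = list(temperature = 1.0, gap_mode = "affine", gap = -3,
                 open = -3, extend = -0.3, align_mode = "global",
                 restrict_turns = TRUE),
    mrf = list(mask_rate = 0.15, lambda_v = 0.01, lambda_w = 0.001),
    train = list(basic_align_steps = 30L, train_mrf_steps = 150L,
                 learning_rate = 0.01, encoder_learning_rate = 0.001,
                 basic_align_learning_rate = 0.003,
                 batch_size = NULL, init_gain = 2, coverage_weight = 4),
    eval = list(min_sep = 6L, gap_open = -11, gap_extend = -1),
    simulate = list(L = 30L, n_seqs = 100L, n_contacts = 20L,
                    strength = 3, ins_rate = 0.05, del_rate = 0.05,
                    sweeps = 30L, field_sd = 3.0, contact_field_sd = 1.5)
  ), class = "smurf_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_config()]; keys that do not exist in the defaults are
#' rejected.
#'
#' @param path Path to a YAML file (may be `NULL` for pure defaults).
#' @param seed Seed override (takes precedence over the file).
#' @return A `smurf_config` list.
#' @export
read_config <- function(path = NULL, seed = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "")
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) stop("a seed is mandatory", call. = FALSE)
  class(cfg) <- "smurf_config"
  cfg
}

merge_config <- function(base, user, prefix) {
  if (is.null(user)) return(base)
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!(key %in% names(base))) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[key] <- list(user[[key]])
    }
  }
  base
}

# translate a nested run config into the flat train_config used by the
# training loops
config_train <- function(cfg, phase = c("train_mrf", "basic_align")) {
  phase <- match.arg(phase)
  steps <- if (phase == "basic_align") cfg$train$basic_align_steps
           else cfg$train$train_mrf_steps
  train_config(
    learning_rate = if (phase == "basic_align")
      cfg$train$basic_align_learning_rate else cfg$train$learning_rate,
    steps = steps,
    batch_size = cfg$train$batch_size,
    temperature = cfg$align$temperature,
    seed = cfg$seed,
    mask_rate = cfg$mrf$mask_rate,
    lambda_v = cfg$mrf$lambda_v,
    lambda_w = cfg$mrf$lambda_w,
    filters = cfg$encoder$filters,
    window_half_width = cfg$encoder$window_half_width,
    open = if (cfg$align$gap_mode == "affine") cfg$align$open else cfg$align$gap,
    extend = if (cfg$align$gap_mode == "affine") cfg$align$extend else cfg$align$gap,
    align_mode = cfg$align$align_mode,
    restrict_turns = cfg$align$restrict_turns,
    encoder_learning_rate = cfg$train$encoder_learning_rate,
    init_gain = cfg$train$init_gain,
    coverage_weight = cfg$train$coverage_weight
  )
}

config_align_params <- function(cfg) {
  align_params(temperature = cfg$align$temperature,
               gap = cfg$align$gap,
               open = cfg$align$open, extend = cfg$align$extend,
               gap_mode = cfg$align$gap_mode,
               align_mode = cfg$align$align_mode,
               restrict_turns = cfg$align$restrict_turns)
}
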