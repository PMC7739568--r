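#' Default pipeline configuration
#'
#' All tunables of the detection pipeline, the evaluation and the simulator
#' in one nested list. The filter cut-offs (0.5 Hz decision, 3.0 Hz fine
#' tuning), the rule-1 time bounds (0.3 s, 5.0 s) and the neighborhood
#' fraction `p = 0.6` are the method's published constants; the rate
#' thresholds are calibrated tunables (see [labeling_params()]).
#'
#' @return Nested named list. See `inst/extdata/default_config.yaml` for the
#'   serialized form.
#' @export
default_config <- function() {
  list(
    sampling = list(
      fs = 64,            # resampling rate, Hz
      units = "rad/s",    # "rad/s" or "deg/s" (input conversion)
      roll_axis = "z",    # boot axis carrying edging rotations
      roll_sign = 1,      # +1 posterior-positive mounting, -1 flipped
      max_gap_s = 0.5     # transmission gaps longer than this split the recording
    ),
    filter = list(
      base_order = 2,     # single-pass order; forward-backward doubles it
      fc_decision = 0.5,  # Hz
      fc_fine = 3.0       # Hz
    ),
    labeling = list(
      min_switch_rate = 0.2,    # rad/s, rule 1
      min_gap = 0.3,            # s, rule 1
      max_gap = 5.0,            # s, rule 1
      low_rate_threshold = 0.1, # rad/s, rule 3a
      theta1 = 0.05,            # rad/s, rule 3c
      theta2 = 1.0              # s, rule 3c
    ),
    fine_tune = list(p = 0.6),
    direction_convention = "opening",
    evaluation = list(
      matching = "greedy",          # or "optimal"
      default_turn_duration = 2.0   # s, tolerance fallback for runs with < 2 references
    ),
    simulator = default_sim_config()
  )
}

#' Load a YAML configuration, merged over the defaults
#'
#' Keys present in the file override the defaults recursively; unknown keys
#' are rejected so typos cannot silently fall back to a default.
#'
#' @param path YAML file, or `NULL` for the pure defaults.
#' @return Config list as from [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_input("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user, keypath = character(0))
}

merge_config <- function(base, user, keypath) {
  if (!is.list(user)) return(user)
  for (k in names(user)) {
    where <- paste(c(keypath, k), collapse = "$")
    if (!k %in% names(base)) {
      stop_input("unknown config key: ", where)
    }
    # leaf lists such as simulator$segments are replaced wholesale
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], c(keypath, k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

# labeling sub-config -> labeling_params
config_labeling_params <- function(cfg) {
  do.call(labeling_params, cfg$labeling)
}
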