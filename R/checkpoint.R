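# Portable model checkpoint: a single JSON file carrying a versioned
# header, the alphabet, the reservoir configuration, the frozen group gains
# and the flat weight arrays. Adam moment buffers are not persisted; a
# reloaded model is an inference checkpoint.

.ckpt_version <- "volamp-ckpt-1"

#' Save a trained model to a JSON checkpoint
#'
#' @param model A `volamp_model` from [fit_readout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "volamp_model"))
  net <- model$net
  cfg <- model$config
  payload <- list(
    version = .ckpt_version,
    alphabet = as.character(model$alphabet),
    shapes = list(n_in = net$n_in, n_hidden = net$n_hidden, n_out = net$n_out),
    gains = list(gains = as.numeric(model$gains$gains),
                 scale = model$gains$scale,
                 n_groups = model$gains$n_groups, block = model$gains$block),
    reservoir = list(duties = cfg$duties, set_amplitude = cfg$set_amplitude,
                     unit_slot = cfg$unit_slot, read_v = cfg$read_v,
                     read_width = cfg$read_width,
                     slot_time_scale = cfg$slot_time_scale),
    device = list(g_off_ns = cfg$params$g_off * 1e9,
                  g_on_ns = cfg$params$g_on * 1e9,
                  tau_ref_ms = cfg$params$tau_ref * 1e3,
                  ea_ev = cfg$params$ea, t_ref_k = cfg$params$t_ref,
                  rectification_ratio = cfg$params$rectification_ratio),
    weights = list(w1 = as.numeric(net$w1), b1 = as.numeric(net$b1),
                   w2 = as.numeric(net$w2), b2 = as.numeric(net$b2)),
    loss_history = model$loss_history,
    training = list(epochs = model$epochs, lr = model$lr, seed = model$seed)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_model()].
#' @return A `volamp_model` (without optimizer state).
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$version, .ckpt_version))
    stop("unsupported checkpoint version: ", p$version)
  sh <- p$shapes
  net <- list(w1 = matrix(p$weights$w1, sh$n_in, sh$n_hidden),
              b1 = p$weights$b1,
              w2 = matrix(p$weights$w2, sh$n_hidden, sh$n_out),
              b2 = p$weights$b2,
              n_in = sh$n_in, n_hidden = sh$n_hidden, n_out = sh$n_out,
              adam = NULL, step = 0L)
  class(net) <- "readout_net"
  gains <- structure(list(gains = p$gains$gains, scale = p$gains$scale,
                          n_groups = p$gains$n_groups, block = p$gains$block),
                     class = "group_gains")
  cfg <- reservoir_config(
    duties = p$reservoir$duties, set_amplitude = p$reservoir$set_amplitude,
    unit_slot = p$reservoir$unit_slot, read_v = p$reservoir$read_v,
    read_width = p$reservoir$read_width,
    slot_time_scale = p$reservoir$slot_time_scale,
    params = device_params(g_off_ns = p$device$g_off_ns,
                           g_on_ns = p$device$g_on_ns,
                           tau_ref_ms = p$device$tau_ref_ms,
                           ea_ev = p$device$ea_ev, t_ref_k = p$device$t_ref_k,
                           rectification_ratio = p$device$rectification_ratio))
  structure(list(net = net, gains = gains,
                 alphabet = structure(p$alphabet, class = "volamp_alphabet"),
                 config = cfg, loss_history = p$loss_history,
                 lr = p$training$lr, epochs = p$training$epochs,
                 seed = p$training$seed),
            class = "volamp_model")
}
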