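# End-to-end orchestration: synthetic (or user) corpus -> reservoir +
# readout training -> autoregressive generation -> physicochemical
# evaluation, with every artifact and the resolved configuration written
# next to each other and all randomness derived from one global seed.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full training/generation/evaluation pipeline
#'
#' Stages: corpus (synthetic via [generate_corpus()] unless
#' `config$corpus_file` points at a FASTA/text file), training
#' ([fit_readout()]), generation ([generate_set()]), evaluation
#' ([compare_sets()] of generated vs training set). Writes `model.json`,
#' `generated.fasta`, `evaluation.json`, `config.json` and `run_log.txt`
#' into `outdir`. Two runs with the same configuration are byte-identical.
#'
#' @param config Configuration list, see [default_config()].
#' @param outdir Output directory (created if needed).
#' @return Named list of artifact paths, invisibly; the trained model is
#'   attached as attribute `model`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("volamp_")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  corpus <- .stage("read_sequences", {
    if (!is.null(config$corpus_file)) read_sequences(config$corpus_file)
    else {
      sp <- config$synth
      generate_corpus(corpus_spec(
        n_sequences = sp$n_sequences, length_range = sp$length_range,
        target_charge = sp$target_charge,
        amphipathic_period = sp$amphipathic_period, seed = seed))
    }
  })

  model <- .stage("train", {
    rc <- reservoir_config(duties = config$reservoir$duties,
                           set_amplitude = config$reservoir$set_amplitude,
                           slot_time_scale = config$reservoir$slot_time_scale)
    fit_readout(corpus, config = rc, epochs = config$readout$epochs,
                lr = config$readout$lr, n_hidden = config$readout$n_hidden,
                corpus_alphabet = isTRUE(config$readout$corpus_alphabet),
                seed = seed)
  })

  generated <- .stage("generate", {
    generate_set(model, n = config$generation$n, training_corpus = corpus,
                 rng_seed = seed + 1L, max_len = config$generation$max_len)
  })

  evaluation <- .stage("evaluate", {
    cm <- charge_model(pH = config$eval$pH)
    cmp <- compare_sets(as.character(generated), corpus, cm)
    list(
      n_training = length(corpus), n_generated = length(generated),
      generated = list(mean_charge = unname(cmp$mean_charge["a"]),
                       mean_mw = unname(cmp$mean_mw["a"])),
      training = list(mean_charge = unname(cmp$mean_charge["b"]),
                      mean_mw = unname(cmp$mean_mw["b"])),
      l1_distribution_distance = cmp$l1_distance,
      pH = cm$pH, pKa = as.list(cm$pKa)
    )
  })

  paths <- list(model = file.path(outdir, "model.json"),
                generated = file.path(outdir, "generated.fasta"),
                evaluation = file.path(outdir, "evaluation.json"),
                config = file.path(outdir, "config.json"),
                log = file.path(outdir, "run_log.txt"))
  save_model(model, paths$model)
  write_generated_fasta(generated, paths$generated)
  jsonlite::write_json(evaluation, paths$evaluation, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(config, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")
  taus <- vapply(config$reservoir$duties, function(d)
    tau_effective(model$config$params, d) * 1e3, numeric(1))
  writeLines(c(
    sprintf("volamp %s pipeline run", as.character(utils::packageVersion("volamp"))),
    sprintf("seed: %d (generation seed %d)", seed, seed + 1L),
    sprintf("corpus: %d sequences", length(corpus)),
    sprintf("duty -> tau map: %s",
            paste(sprintf("%.2f -> %.3g ms", config$reservoir$duties, taus),
                  collapse = ", ")),
    sprintf("optimizer: Adam lr %g, %d epochs, online (batch 1)",
            config$readout$lr, config$readout$epochs),
    sprintf("charge model: pH %g, Bjellqvist pKa table", config$eval$pH),
    sprintf("final mean training loss: %.5f",
            utils::tail(model$loss_history, 1))
  ), paths$log)
  attr(paths, "model") <- model
  invisible(paths)
}
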