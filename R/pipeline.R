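# End-to-end orchestration: simulate -> prepare -> train -> basecall ->
# evaluate, with on-disk artifacts, seeds and a reproducibility manifest.
#
# Dataset recipe (mirrors the reduced-complexity design): every dataset is
# built from two equal-length sequences drawn from the same 6-mer basis - one
# used entirely for training, the other split into validation and test parts.

#' Pipeline run configuration
#'
#' Defaults follow the published processing parameters: rawmax 200, eventmax
#' 30, batch size 128, latent width 128, gradient clip 1, scheduled-sampling
#' ratio 0.5.
#'
#' @param out_dir artifact directory
#' @param num_basic basis size for simulation
#' @param total_length bases per sequence (two sequences are generated)
#' @param read_length bases per simulated read
#' @param dwell_mean,noise_sd pore-model parameters
#' @param window,threshold event detection parameters
#' @param rawmax,eventmax,eventoffset sample construction parameters
#' @param eval_fractions `(test, validation, train)` fractions for the
#'   evaluation sequence's samples
#' @param mode model mode ("joint", "raw" or "event")
#' @param latent_dim,epochs,batch_size,lr,clip_norm,sampling_ratio training
#'   hyper-parameters
#' @param beam_width decoding beam width (1 = greedy)
#' @param seed master seed
#' @return list of class `run_config`
#' @export
run_config <- function(out_dir = "squigglecall_run",
                       num_basic = 12L, total_length = 3000L,
                       read_length = 300L, dwell_mean = 8, noise_sd = 2.0,
                       window = 7L, threshold = 4.0,
                       rawmax = 200L, eventmax = 30L, eventoffset = 1L,
                       eval_fractions = c(0.75, 0.25, 0),
                       mode = "joint", latent_dim = 128L, epochs = 10L,
                       batch_size = 128L, lr = 1e-3, clip_norm = 1.0,
                       sampling_ratio = 0.5, beam_width = 1L, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

manifest_write <- function(config, out_dir, stage) {
  man <- list(
    package = "squigglecall",
    version = as.character(utils::packageVersion("squigglecall")),
    r_version = R.version.string,
    stage = stage,
    config = unclass(config),
    config_hash = digest_config(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

digest_config <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  # small stable polynomial hash mod 2^32; avoids an external digest
  # dependency (double arithmetic stays below 2^53)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

sim_one_side <- function(config, basis, seed_offset, id_prefix) {
  model <- pore_model(seed = config$seed, dwell_mean = config$dwell_mean,
                      noise_sd = config$noise_sd)
  ref <- generate_reference(basis, config$total_length,
                            seed = config$seed + seed_offset)
  n_reads <- config$total_length / config$read_length
  reads <- lapply(seq_len(n_reads), function(i) {
    sub <- substr(ref$sequence, (i - 1L) * config$read_length + 1L,
                  i * config$read_length)
    simulate_signal(sub, model, seed = config$seed + seed_offset + 100L + i,
                    read_id = sprintf("%s_%04d", id_prefix, i))
  })
  list(reference = ref$sequence, reads = reads)
}

stage_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(config$total_length %% config$read_length == 0)
  basis <- generate_kmer_basis(config$num_basic, seed = config$seed)
  train <- sim_one_side(config, basis, 1L, "train")
  eval_ <- sim_one_side(config, basis, 2L, "eval")
  for (side in list(list(nm = "train", d = train), list(nm = "eval", d = eval_))) {
    base <- file.path(config$out_dir, side$nm)
    write_fast5(side$d$reads, paste0(base, "_reads.fast5"))
    write_fasta(stats::setNames(
      lapply(side$d$reads, `[[`, "reference"),
      vapply(side$d$reads, `[[`, "", "read_id")), paste0(base, "_refs.fasta"))
    write_truth_tsv(side$d$reads, paste0(base, "_truth.tsv"))
  }
  invisible(list(train = train, eval = eval_))
}

load_side <- function(config, side) {
  base <- file.path(config$out_dir, side)
  f5 <- read_fast5(paste0(base, "_reads.fast5"))
  refs <- read_fasta(paste0(base, "_refs.fasta"))
  truth <- read_truth_tsv(paste0(base, "_truth.tsv"))
  reads <- lapply(f5, function(r) {
    structure(list(read_id = r$read_id, signal = r$signal,
                   reference = refs[[r$read_id]],
                   truth_ranges = truth[[r$read_id]]),
              class = "raw_read")
  })
  reads[order(vapply(reads, `[[`, "", "read_id"))]
}

stage_prepare <- function(config) {
  need <- file.path(config$out_dir, "train_reads.fast5")
  if (!file.exists(need))
    stop("missing artifact ", need, "; run the 'simulate' stage first")
  params <- event_params(config$window, config$threshold)
  build_all <- function(reads) {
    out <- list()
    for (r in reads) {
      ev <- detect_events(r$signal, params)
      out <- c(out, build_samples(r, ev, config$rawmax, config$eventmax,
                                  config$eventoffset))
    }
    out[vapply(out, function(s) length(s$tokens) > 2L, logical(1L))]
  }
  train_samples <- build_all(load_side(config, "train"))
  eval_samples <- build_all(load_side(config, "eval"))
  scalers <- fit_scalers(train_samples)
  ev_split <- split_dataset(eval_samples, config$eval_fractions,
                            seed = config$seed)
  target_len <- max(vapply(train_samples, function(s) length(s$tokens),
                           1L)) + 2L
  cache <- list(train = apply_scalers(train_samples, scalers),
                validation = apply_scalers(ev_split$validation, scalers),
                test = apply_scalers(ev_split$test, scalers),
                scalers = scalers, target_len = target_len)
  saveRDS(cache, file.path(config$out_dir, "dataset.rds"))
  invisible(cache)
}

stage_train <- function(config) {
  cache_path <- file.path(config$out_dir, "dataset.rds")
  if (!file.exists(cache_path))
    stop("missing artifact ", cache_path, "; run the 'prepare' stage first")
  cache <- readRDS(cache_path)
  mcfg <- model_config(latent_dim = config$latent_dim, mode = config$mode,
                       rawmax = config$rawmax, eventmax = config$eventmax)
  model <- init_model(mcfg, seed = config$seed)
  tc <- train_config(epochs = config$epochs, batch_size = config$batch_size,
                     lr = config$lr, clip_norm = config$clip_norm,
                     sampling_ratio = config$sampling_ratio,
                     seed = config$seed)
  fit <- train_model(model, cache$train, cache$validation, tc,
                     target_len = cache$target_len)
  checkpoint <- list(params = fit$model$params, config = mcfg,
                     scalers = cache$scalers, tokenizer = tokenizer(),
                     train_log = fit$log)
  saveRDS(checkpoint, file.path(config$out_dir, "checkpoint.rds"))
  utils::write.table(fit$log, file.path(config$out_dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fit)
}

#' Load a saved checkpoint as a usable model
#' @param path checkpoint file from the train stage
#' @return list with `model` (a `squiggle_model`) and `scalers`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- structure(list(config = ck$config, params = ck$params),
                     class = "squiggle_model")
  list(model = model, scalers = ck$scalers, train_log = ck$train_log)
}

stage_basecall <- function(config) {
  ck_path <- file.path(config$out_dir, "checkpoint.rds")
  if (!file.exists(ck_path))
    stop("missing artifact ", ck_path, "; run the 'train' stage first")
  ck <- load_checkpoint(ck_path)
  if (ck$model$config$mode != config$mode)
    stop(sprintf("checkpoint mode '%s' does not match configured mode '%s'",
                 ck$model$config$mode, config$mode))
  reads <- load_side(config, "eval")
  params <- event_params(config$window, config$threshold)
  calls <- lapply(reads, function(r)
    basecall_read(ck$model, r$signal, ck$scalers, params,
                  eventoffset = 6L, beam_width = config$beam_width,
                  read_id = r$read_id))
  write_fasta(stats::setNames(lapply(calls, `[[`, "sequence"),
                              vapply(calls, `[[`, "", "read_id")),
              file.path(config$out_dir,
                        sprintf("basecalls_beam%d.fasta", config$beam_width)))
  invisible(calls)
}

stage_evaluate <- function(config) {
  bc_path <- file.path(config$out_dir,
                       sprintf("basecalls_beam%d.fasta", config$beam_width))
  if (!file.exists(bc_path))
    stop("missing artifact ", bc_path, "; run the 'basecall' stage first")
  calls <- read_fasta(bc_path)
  refs <- read_fasta(file.path(config$out_dir, "eval_refs.fasta"))
  reads <- lapply(names(calls), function(id)
    structure(list(read_id = id, sequence = calls[[id]], n_samples = NA),
              class = "assembled_read"))
  rep <- evaluate_reads(reads, refs)
  jsonlite::write_json(
    list(weighted_identity = rep$weighted_identity,
         per_read = rep$per_read),
    file.path(config$out_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(rep$per_read,
                     file.path(config$out_dir, "evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' Run the basecalling pipeline
#'
#' Executes the requested stages in order.  Each stage reads its inputs from
#' `config$out_dir` and writes its artifacts there; a missing upstream
#' artifact produces an error naming the stage to run.  A manifest
#' (config, hash, versions) is written after every invocation.
#'
#' @param config a `run_config`
#' @param stages subset of c("simulate", "prepare", "train", "basecall",
#'   "evaluate")
#' @return invisibly, the last stage's result
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "prepare", "train",
                                    "basecall", "evaluate")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "prepare", "train", "basecall", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  res <- NULL
  for (st in stages) {
    res <- switch(st,
                  simulate = stage_simulate(config),
                  prepare = stage_prepare(config),
                  train = stage_train(config),
                  basecall = stage_basecall(config),
                  evaluate = stage_evaluate(config))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_write(config, config$out_dir, stages[length(stages)])
  invisible(res)
}
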