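#' Train the full two-stage generative model on a cohort
#'
#' Executes the training pipeline in order: derive masks; one-hot encode
#' categoricals and train the static and temporal codecs; fit the
#' stochastic normalizers on observed values; assemble the model-space
#' bundle; train the masked sequential autoencoder; encode the cohort into
#' latent states; train the WGAN-GP over those states. All randomness
#' derives from `config$seed` through named substreams, so a rerun with the
#' same inputs is bit-identical.
#'
#' Ablation switches (all `TRUE` by default): `stochastic_norm = FALSE`
#' replaces the frequency-proportional normalizer with min-max scaling;
#' `mask_modeling = FALSE` drops the mask channels from the model inputs
#' and losses and mean-imputes missing numerics; `categorical_embedding =
#' FALSE` passes raw one-hot blocks through an identity codec.
#'
#' @param data an `ehr_cohort` (training split).
#' @param masks its `ehr_masks`.
#' @param config a [training_config()].
#' @param stochastic_norm,mask_modeling,categorical_embedding ablations.
#' @param max_unique optional cap for [fit_normalizer()].
#' @return an `ehr_generator` bundling every trained component, the
#'   configuration, the ablation flags and the schema.
#' @export
train_ehr_generator <- function(data, masks = derive_masks(data),
                           config = training_config(),
                           stochastic_norm = TRUE, mask_modeling = TRUE,
                           categorical_embedding = TRUE, max_unique = Inf) {
  validate_cohort(data, masks)
  sch <- data$schema
  stage <- "codec"
  out <- tryCatch({
    static_codec <- NULL
    if (length(sch$static_categorical)) {
      static_codec <- if (categorical_embedding)
        train_codec(data$static_cat, sch$static_categorical, scope = "static",
                    epochs = config$cat_epochs,
                    seed = substream_seed(config$seed, "codec-static"))
      else identity_codec(sch$static_categorical, "static")
    }
    temporal_codec <- NULL
    if (length(sch$temporal_categorical)) {
      pres <- which(masks$step_present == 1)
      flat <- matrix(NA_character_, length(pres), length(sch$temporal_categorical),
                     dimnames = list(NULL, names(sch$temporal_categorical)))
      for (kk in seq_along(sch$temporal_categorical))
        flat[, kk] <- data$temporal_cat[, , kk][pres]
      temporal_codec <- if (categorical_embedding)
        train_codec(flat, sch$temporal_categorical, scope = "temporal",
                    epochs = config$cat_epochs,
                    seed = substream_seed(config$seed, "codec-temporal"))
      else identity_codec(sch$temporal_categorical, "temporal")
    }
    stage <- "normalization"
    norm_params <- if (stochastic_norm)
      fit_cohort_normalizers(data, masks, max_unique)
    else fit_cohort_minmax(data, masks)
    stage <- "assembly"
    bundle <- assemble_inputs(data, masks, norm_params, static_codec,
                              temporal_codec, seed = config$seed,
                              mask_modeling = mask_modeling)
    stage <- "autoencoder"
    ae <- train_autoencoder(bundle, config)
    stage <- "latents"
    latents <- encode_dataset(bundle, ae)
    stage <- "residuals"
    resid_sd <- residual_sds(ae, latents, bundle)
    stage <- "gan"
    gan <- train_wgan_gp(latents, config)
    structure(list(schema = sch, config = config, norm_params = norm_params,
                   residual_sd = resid_sd, static_codec = static_codec,
                   temporal_codec = temporal_codec, autoencoder = ae,
                   gan = gan, latents = latents,
                   flags = list(stochastic_norm = stochastic_norm,
                                mask_modeling = mask_modeling,
                                categorical_embedding = categorical_embedding)),
              class = "ehr_generator")
  }, error = function(e) {
    stop("training failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  out
}

#' Min-max normalizer set (ablation counterpart of
#' [fit_cohort_normalizers()])
#' @param data an `ehr_cohort`.
#' @param masks its `ehr_masks`.
#' @return a `minmax_set` of per-feature `minmaxnorm` objects.
#' @export
fit_cohort_minmax <- function(data, masks) {
  sch <- data$schema
  out <- list()
  for (f in sch$static_numeric)
    out[[f]] <- fit_minmax(data$static_num[, f][masks$m_sn[, f] == 1])
  for (f in sch$temporal_numeric)
    out[[f]] <- fit_minmax(data$temporal_num[, , f][masks$m_tn[, , f] == 1])
  out[[sch$time_name]] <- fit_minmax(data$time[masks$step_present == 1])
  class(out) <- "minmax_set"
  out
}

#' Save / load a trained model container
#'
#' Runtime serialization of the full component bundle (codecs, normalizers,
#' autoencoder, generator, configuration and schema) to a single file.
#'
#' @param model an `ehr_generator`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ehr_generator"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ehr_generator"))
  m
}

#' Full evaluation of a trained model against real splits
#'
#' Synthesizes as many records as the real training split, then computes
#' the per-feature similarity table, train-on-synthetic/test-on-real
#' utility, the random-subset utility test, and the three privacy attacks
#' (membership inference, re-identification with its holdout baseline, and
#' attribute inference).
#'
#' @param model an `ehr_generator`.
#' @param real_train,real_holdout lists with `data`/`masks`.
#' @param targets binary targets for the utility metrics.
#' @param attributes features for attribute inference.
#' @param n_query membership-attack query size per arm.
#' @param subset_features,subset_trials random-subset test settings.
#' @param seed master evaluation seed.
#' @param synth optional pre-generated synthetic cohort (list with
#'   `data`/`masks`); when `NULL`, `m = n_records(real_train)` records are
#'   synthesized. Passing `real_holdout` here is the re-identification
#'   oracle mode, which returns risk equal to its baseline exactly.
#' @return a list: `synth`, `similarity`, `utility`, `subset_test`,
#'   `privacy`.
#' @export
run_eval <- function(model, real_train, real_holdout,
                     targets = c("mortality", "gender"),
                     attributes = "marital_status", n_query = 500L,
                     subset_features = 8L, subset_trials = 5L, seed = 1L,
                     synth = NULL) {
  if (is.null(synth))
    synth <- synthesize(model, n_records(real_train$data), seed = seed)
  sim <- summary_table(real_train, synth)
  util <- list()
  for (tg in targets)
    util[[tg]] <- tstr_utility(real_train, synth, real_holdout, tg,
                               model_kind = "rf", seed = seed)
  sub <- subset_utility_test(real_train, synth, real_holdout, targets,
                             n_features = subset_features,
                             n_trials = subset_trials, seed = seed)
  n_t <- n_records(real_train$data)
  n_h <- n_records(real_holdout$data)
  nq <- min(n_query, n_t, n_h)
  qt <- with_substream(seed, "mi-train-queries",
                       sort(sample.int(n_t, nq)))
  qh <- with_substream(seed, "mi-holdout-queries",
                       sort(sample.int(n_h, nq)))
  sub_pair <- function(x, idx) list(data = subset_cohort(x$data, idx),
                                    masks = derive_masks(subset_cohort(x$data, idx)))
  mi <- membership_inference(synth, sub_pair(real_train, qt),
                             sub_pair(real_holdout, qh))
  reid <- reidentification_risk(synth, real_train, real_holdout, seed = seed)
  attr_res <- lapply(attributes, function(a)
    attribute_inference(synth, real_train, real_holdout, a))
  names(attr_res) <- attributes
  list(synth = synth, similarity = sim, utility = util, subset_test = sub,
       privacy = list(membership = mi, reidentification = reid,
                      attribute = attr_res))
}
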