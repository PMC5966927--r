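#' Configuration of an end-to-end triage run
#'
#' Bundles every stage's settings behind one object with a single global
#' seed; each stage derives its own seed deterministically from the global
#' one (a hash of the stage name mixed into the seed), so a run is
#' reproducible end to end and the whole configuration is serialized next to
#' its outputs.
#'
#' @param manifest Path to the case manifest CSV.
#' @param out_dir Output directory for all run artifacts.
#' @param side Working image side length after preprocessing (multiple of 8).
#' @param train_fraction Training fraction of the random split.
#' @param balance Feature-space rebalancing of the training set: `"none"`,
#'   `"smote"`, `"smote_tk"` or `"smote_enn"`.
#' @param augment Image-space augmentation of the training set: `"none"`,
#'   `"positive"` (3 rotated/shifted copies of every abnormal training
#'   case), or `"4x"` (3 copies of every training case).
#' @param head_epochs,csdae_epochs Training epochs of the two branches.
#' @param csdae_noise Noise factor of the denoising autoencoder.
#' @param head_loss Loss of the classifier head (`"focal"` or
#'   `"cross_entropy"`).
#' @param vote_threshold Probability cut turning panel probabilities into
#'   binary votes.
#' @param grid_sizes `(T, P)` grid sizes of the threshold-rule search.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest, out_dir, side = 64, train_fraction = 0.7,
                       balance = c("none", "smote", "smote_tk", "smote_enn"),
                       augment = c("none", "positive", "4x"),
                       head_epochs = 100, csdae_epochs = 30,
                       csdae_noise = 0.01,
                       head_loss = c("focal", "cross_entropy"),
                       vote_threshold = 0.5, grid_sizes = c(25, 25),
                       seed = 1) {
  balance <- match.arg(balance)
  augment <- match.arg(augment)
  head_loss <- match.arg(head_loss)
  structure(list(manifest = manifest, out_dir = out_dir,
                 side = as.integer(side), train_fraction = train_fraction,
                 balance = balance, augment = augment,
                 head_epochs = as.integer(head_epochs),
                 csdae_epochs = as.integer(csdae_epochs),
                 csdae_noise = csdae_noise, head_loss = head_loss,
                 vote_threshold = vote_threshold, grid_sizes = grid_sizes,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_stage <- function(name, code) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  out <- tryCatch(force(code), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full triage pipeline
#'
#' Executes the five stages in order — preprocessing (histogram
#' equalization, lung-box crop, bilinear down-sampling), lung masks
#' (external when the manifest provides them, fallback segmentation
#' otherwise), feature extraction plus classifier training (the head and the
#' four baselines), autoencoder training on the *normal training cases
#' only*, and score combination / threshold search / three-level vote — and
#' writes every artifact (split, features, scores, triage labels, evaluation
#' reports, run config) into `out_dir`. Reruns with the same configuration
#' and seed are byte-identical.
#'
#' @param config A [run_config()].
#' @return A list with the run directory, scores, triage tibble and
#'   evaluation objects, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- pipeline_stage("manifest", read_manifest(config$manifest))

  prepped <- pipeline_stage("preprocess", {
    purrr::pmap(manifest, function(case_id, path, label, ...) {
      dots <- list(...)
      img <- tryCatch(load_image(path), error = function(e) {
        stop(sprintf("case %s: %s", case_id, conditionMessage(e)),
             call. = FALSE)
      })
      eq <- equalize_histogram(img)
      mask <- if (!is.null(dots$mask_path) && !is.na(dots$mask_path) &&
                  nzchar(dots$mask_path)) {
        m <- load_image(dots$mask_path)
        matrix(as.integer(m > 0.5), nrow(m))
      } else {
        segment_lungs_fallback(eq)
      }
      resize_image(clip01(crop_to_mask_bbox(eq, mask)), config$side)
    })
  })
  images <- tibble::tibble(case_id = manifest$case_id,
                           label = manifest$label, image = prepped)

  split <- pipeline_stage("split", {
    s <- split_dataset(manifest$case_id, config$train_fraction,
                       seed = stage_seed(config$seed, "split"))
    readr::write_csv(s, file.path(config$out_dir, "split.csv"))
    s
  })
  is_train <- split$partition[match(images$case_id, split$case_id)] == "train"

  aug_images <- NULL
  if (config$augment != "none") {
    aug_images <- pipeline_stage("augment", {
      idx <- which(is_train &
                     (config$augment == "4x" | images$label == 1L))
      copies <- purrr::map(seq_along(rep(idx, each = 3)), function(k) {
        i <- rep(idx, each = 3)[k]
        augment_image(images$image[[i]],
                      augment_spec(seed = stage_seed(config$seed,
                                                     paste0("aug_", k))))
      })
      tibble::tibble(
        case_id = paste0(rep(images$case_id[idx], each = 3), "_aug",
                         rep(1:3, length(idx))),
        label = rep(images$label[idx], each = 3),
        image = copies)
    })
  }

  feats_res <- pipeline_stage("features", {
    f <- extract_features_dataset(images)
    train_pool <- f[is_train, , drop = FALSE]
    if (!is.null(aug_images)) {
      train_pool <- dplyr::bind_rows(train_pool,
                                     extract_features_dataset(aug_images))
    }
    norm <- normalize_features(train_pool, f)
    readr::write_csv(norm, file.path(config$out_dir, "features.csv"))
    list(all = norm, train_pool = normalize_features(train_pool))
  })
  feats <- feats_res$all
  train_feats <- feats_res$train_pool
  if (config$balance != "none") {
    train_feats <- pipeline_stage("rebalance", {
      out <- smote(train_feats, seed = stage_seed(config$seed, "smote"))
      switch(config$balance,
             smote = out,
             smote_tk = tomek_remove(out),
             smote_enn = enn_clean(out))
    })
  }

  head_model <- pipeline_stage("train_head", {
    train_head(train_feats, config = head_config(
      loss = config$head_loss, epochs = config$head_epochs,
      seed = stage_seed(config$seed, "head")))
  })
  baselines <- pipeline_stage("baselines", {
    fit_baselines(train_feats, seed = stage_seed(config$seed, "baselines"))
  })

  csdae_model <- pipeline_stage("train_csdae", {
    train_normals <- images$image[is_train & images$label == 0L]
    train_autoencoder(train_normals, csdae_config(
      epochs = config$csdae_epochs, noise_factor = config$csdae_noise,
      seed = stage_seed(config$seed, "csdae")))
  })

  scores <- pipeline_stage("scores", {
    s <- tibble::tibble(
      case_id = images$case_id,
      prob = predict_proba(head_model, feats),
      recon_error = reconstruction_error(csdae_model, images$image),
      label = images$label)
    readr::write_csv(s, file.path(config$out_dir, "scores.csv"))
    s
  })
  train_scores <- scores[is_train, , drop = FALSE]
  test_scores <- scores[!is_train, , drop = FALSE]

  decision <- pipeline_stage("combine_decide", {
    combo <- fit_combination(train_scores[c("prob", "recon_error", "label")])
    t_mean <- mean(reconstruction_error(
      csdae_model, images$image[is_train & images$label == 0L]))
    rule <- fit_threshold_rule(train_scores$prob, train_scores$recon_error,
                               train_scores$label, t_mean = t_mean,
                               grid_sizes = config$grid_sizes)
    test_feats <- feats[!is_train, , drop = FALSE]
    votes <- cbind(
      purrr::map_dfc(baselines, function(b) {
        as.integer(predict_proba(b, test_feats) > config$vote_threshold)
      }),
      head = as.integer(test_scores$prob > config$vote_threshold),
      rule = as.integer(predict(rule, test_scores$prob,
                                test_scores$recon_error) >= 1)
    )
    levels <- triage_vote(votes)
    triage <- tibble::tibble(case_id = test_scores$case_id, level = levels,
                             prob = test_scores$prob,
                             recon_error = test_scores$recon_error)
    readr::write_csv(triage, file.path(config$out_dir, "triage.csv"))
    list(combo = combo, rule = rule, triage = triage)
  })

  reports <- pipeline_stage("evaluate", {
    eval_head <- evaluate_binary(NULL, test_scores$label,
                                 scores = test_scores$prob)
    combo_auc <- if (length(unique(test_scores$label)) == 2L) {
      auc_from_labels(predict(decision$combo, test_scores),
                      test_scores$label)
    } else {
      NA_real_
    }
    eval_triage <- evaluate_triage(decision$triage$level, test_scores$label)
    write_report(eval_head, file.path(config$out_dir, "eval_head.json"))
    write_report(eval_triage, file.path(config$out_dir, "eval_triage.json"))
    list(head = eval_head, combo_auc = combo_auc, triage = eval_triage)
  })

  cfg <- unclass(config)
  write_report(cfg, file.path(config$out_dir, "run_config.json"))
  invisible(list(out_dir = config$out_dir, scores = scores,
                 split = split, triage = decision$triage,
                 combination = decision$combo, rule = decision$rule,
                 head = head_model, csdae = csdae_model,
                 evaluation = reports))
}
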