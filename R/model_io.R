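# Model persistence: a self-describing JSON archive (schema version,
# feature manifest, standardizer statistics, Nystroem landmarks and map,
# support vectors, dual coefficients, rho). Doubles are encoded as
# %.17g strings so that load(save(m)) reproduces predictions bit-
# identically.

num_encode <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) {
    list(dim = dim(x), data = sprintf("%.17g", as.numeric(x)))
  } else {
    sprintf("%.17g", as.numeric(x))
  }
}
num_decode <- function(x) {
  if (is.null(x)) return(NULL)
  # %.17g writes missing values as the literal string "NA"
  to_num <- function(v) {
    v <- unlist(v)
    if (is.character(v)) v[v == "NA"] <- NA_character_
    as.numeric(v)
  }
  if (is.list(x) && !is.null(x$dim)) {
    matrix(to_num(x$data), nrow = x$dim[[1L]], ncol = x$dim[[2L]])
  } else {
    to_num(x)
  }
}

#' Save / load a curation model
#'
#' @param model A `curation_model` from [fit_final()].
#' @param path Archive path (JSON).
#' @return `save_model`: invisibly `path`; `load_model`: the restored
#'   `curation_model`, predicting bit-identically to the saved one.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "curation_model")) stop_validation("not a curation model")
  ny <- model$nystrom
  payload <- list(
    schema = model$schema,
    feature_names = model$feature_names,
    scaler = list(mean = num_encode(model$scaler$mean),
                  sd = num_encode(model$scaler$sd)),
    nystrom = if (is.null(ny)) NULL else list(
      landmarks = num_encode(ny$landmarks),
      map = num_encode(ny$map),
      gamma = num_encode(ny$gamma)),
    rule = list(sv = num_encode(model$rule$sv),
                coefs = num_encode(model$rule$coefs),
                rho = num_encode(model$rule$rho),
                kernel = model$rule$kernel,
                C = num_encode(model$rule$C),
                gamma = num_encode(model$rule$gamma)),
    metadata = model$metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("model file not found: %s", path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop_format(
                        sprintf("cannot parse model archive %s: %s",
                                path, conditionMessage(e))))
  if (!identical(payload$schema, "cellcurator/model/1")) {
    stop_format(sprintf("unsupported or missing model schema in %s", path))
  }
  required <- c("feature_names", "scaler", "rule")
  if (!all(required %in% names(payload)) || is.null(payload$rule$sv)) {
    stop_format(sprintf("model archive %s is incomplete", path))
  }
  ny <- payload$nystrom
  model <- structure(list(
    schema = payload$schema,
    feature_names = as.character(payload$feature_names),
    scaler = list(mean = num_decode(payload$scaler$mean),
                  sd = num_decode(payload$scaler$sd)),
    nystrom = if (is.null(ny) || is.null(ny$landmarks)) NULL else list(
      landmarks = num_decode(ny$landmarks),
      map = num_decode(ny$map),
      gamma = num_decode(ny$gamma)),
    rule = list(sv = num_decode(payload$rule$sv),
                coefs = num_decode(payload$rule$coefs),
                rho = num_decode(payload$rule$rho),
                kernel = payload$rule$kernel,
                C = num_decode(payload$rule$C),
                gamma = num_decode(payload$rule$gamma)),
    metadata = payload$metadata), class = "curation_model")
  names(model$scaler$mean) <- model$feature_names
  names(model$scaler$sd) <- model$feature_names
  model
}

#' Curate a set of detections with a trained model
#'
#' Extracts the 26 features for every record, classifies them, and splits
#' the records into kept (predicted good), discarded (predicted bad) and
#' failed (feature extraction failed; counted separately).
#'
#' @param records A [cell_table()].
#' @param images Frame images (as from [read_image_frames()]).
#' @param model A `curation_model`.
#' @param pixel_size Micrometers per pixel.
#' @return List with `kept`, `discarded`, `failed` (cell tables), `report`
#'   (counts and score summary) and `features` (the scored feature table
#'   with `label` and `score` columns).
#' @export
curate <- function(records, images, model, pixel_size = 1) {
  missing_frames <- setdiff(unique(records$frame), as.integer(names(images)))
  if (length(missing_frames)) {
    stop_validation(sprintf("no image for frame(s): %s",
                            paste(missing_frames, collapse = ", ")))
  }
  if (!nrow(records)) {
    return(list(kept = records, discarded = records, failed = records,
                report = list(n_kept = 0L, n_discarded = 0L, n_failed = 0L,
                              scores = NULL),
                features = NULL))
  }
  feats <- extract_feature_table(records, images, pixel_size)
  fmat <- as.data.frame(feats)[, feature_names(), drop = FALSE]
  complete <- stats::complete.cases(fmat)
  labels <- rep(NA_integer_, nrow(feats))
  scores <- rep(NA_real_, nrow(feats))
  if (any(complete)) {
    pred <- predict_curation(model, as.matrix(fmat[complete, , drop = FALSE]))
    labels[complete] <- pred$labels
    scores[complete] <- pred$scores
  }
  feats$label <- labels
  feats$score <- scores
  kept <- records[complete & labels %in% 1L, , drop = FALSE]
  discarded <- records[complete & labels %in% 0L, , drop = FALSE]
  failed <- records[!complete, , drop = FALSE]
  list(kept = kept, discarded = discarded, failed = failed,
       report = list(n_kept = nrow(kept), n_discarded = nrow(discarded),
                     n_failed = nrow(failed),
                     scores = if (any(complete)) summary(scores[complete]) else NULL),
       features = feats)
}
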