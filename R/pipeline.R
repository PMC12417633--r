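# End-to-end orchestration: configuration, the four demo tasks, metrics,
# PCA projection, hypnogram timelines and energy reports.

.default_config <- function() list(
  seed = 7L,
  out_dir = NULL,
  device = list(a_write = 0.3, slot_duration = 0.2, slot_gap = 0.05,
                tau_decay = NULL, v_write = 1.5, v_read = 1.0,
                v_set = 1.0, v_reset = -1.0, i_off = 10e-12, i_on = 0.5e-9,
                p_nl = 2, sigma_c2c = 0),
  encoder = list(n_bins = 8, out_size = 64, n_mfcc = 13, frame_len = 0.025,
                 hop = 0.010, n_mels = 26, audio_cols = 64, mode = "amplitude"),
  reservoir = list(frame_k = 4),
  readout = list(kind = "both", l2 = 10, epochs = 200, lr = 0.1,
                 momentum = 0.9, split = 0.8),
  data = list(n_per_class = 60, epoch_s = 30, clip_s = 10, fs_eeg = 128,
              fs_audio = 16000, ambient = "none", snr_db = 10))

#' Build a validated run configuration
#'
#' Starts from the package defaults, overlays a YAML file (if given) and a
#' list of overrides. Unknown keys at either level are rejected.
#'
#' @param path optional YAML config file with top-level sections `seed`,
#'   `out_dir`, `device`, `encoder`, `reservoir`, `readout`, `data`.
#' @param overrides optional nested list merged last.
#' @return an object of class `fibrc_run_config`.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- .default_config()
  merge_in <- function(cfg, upd, where = "config") {
    unknown <- setdiff(names(upd), names(cfg))
    if (length(unknown)) stop_config("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
    for (nm in names(upd)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(upd[[nm]]))
        merge_in(cfg[[nm]], upd[[nm]], nm) else upd[[nm]]
    }
    cfg
  }
  if (!is.null(path)) cfg <- merge_in(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_in(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "fibrc_run_config")
}

# materialise device params / reservoir config from a run config
.cfg_device <- function(cfg) {
  d <- cfg$device
  tau <- d$tau_decay %||% (2 * (d$slot_duration + d$slot_gap))
  device_params(a_write = d$a_write, slot_duration = d$slot_duration,
                slot_gap = d$slot_gap, tau_decay = tau, v_write = d$v_write,
                v_read = d$v_read, v_set = d$v_set, v_reset = d$v_reset,
                i_off = d$i_off, i_on = d$i_on, p_nl = d$p_nl,
                sigma_c2c = d$sigma_c2c, seed = cfg$seed)
}
.cfg_reservoir <- function(cfg) {
  reservoir_config(frame_k = cfg$reservoir$frame_k, device_params = .cfg_device(cfg),
                   mode = cfg$encoder$mode)
}

#' Classification metrics from true and predicted labels
#'
#' @param labels_true,labels_pred equal-length label vectors.
#' @param classes class set; labels outside it are an error.
#' @return list with `accuracy`, `confusion` (rows = true classes),
#'   `per_class` (precision/recall/F1/support), and macro averages.
#' @export
evaluate <- function(labels_true, labels_pred, classes = sort(unique(labels_true))) {
  if (length(labels_true) != length(labels_pred)) stop_input("label vectors differ in length")
  bad <- setdiff(unique(c(labels_true, labels_pred)), classes)
  if (length(bad)) stop_input("label(s) outside the class set: ", paste(bad, collapse = ", "))
  tt <- factor(labels_true, classes); pp <- factor(labels_pred, classes)
  cm <- table(true = tt, predicted = pp)
  cm <- matrix(as.numeric(cm), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), NA)
  f1 <- ifelse(is.na(prec) | is.na(rec) | (prec + rec) == 0, NA,
               2 * prec * rec / (prec + rec))
  list(accuracy = sum(tp) / sum(cm),
       confusion = cm,
       per_class = data.frame(class = classes, precision = prec, recall = rec,
                              f1 = f1, support = rowSums(cm), row.names = NULL),
       macro_precision = mean(prec, na.rm = TRUE),
       macro_recall = mean(rec, na.rm = TRUE),
       macro_f1 = mean(f1, na.rm = TRUE),
       n = length(labels_true))
}

#' Project state vectors onto principal components
#'
#' Mean-centred PCA via eigendecomposition of the covariance matrix;
#' components are ordered by explained variance and the sign of each is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param states `fibrc_labeled_states`, list of state vectors, or matrix.
#' @param dims number of components (default 2).
#' @return list with `scores` (n x dims), `loadings`, `explained_variance`
#'   and `total_variance`. If fewer informative components exist than
#'   requested, the available ones are returned.
#' @export
project_states <- function(states, dims = 2) {
  X <- if (inherits(states, "fibrc_labeled_states")) states$X
  else if (is.list(states)) do.call(rbind, lapply(states, as.numeric))
  else as.matrix(states)
  if (nrow(X) < dims + 1) stop_input("need at least dims + 1 states")
  Xc <- sweep(X, 2, colMeans(X))
  S <- stats::cov(Xc)
  eig <- eigen(S, symmetric = TRUE)
  keep <- min(dims, sum(eig$values > max(eig$values) * 1e-12), ncol(X))
  V <- eig$vectors[, seq_len(keep), drop = FALSE]
  for (j in seq_len(keep)) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  list(scores = Xc %*% V, loadings = V,
       explained_variance = eig$values[seq_len(keep)],
       total_variance = sum(eig$values))
}

#' Mean silhouette score of labelled points
#'
#' @param X coordinate matrix (rows = points).
#' @param labels cluster/class labels.
#' @return mean silhouette width over all points (Euclidean distance).
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Render a hypnogram timeline from per-epoch labels
#'
#' Consecutive identical stages are merged into half-open `[start_s, end_s)`
#' intervals. Optionally draws a colour-coded PNG hypnogram.
#'
#' @param labels character vector of per-epoch stage labels.
#' @param epoch_s epoch length, seconds.
#' @param csv_path optional output CSV (`start_s,end_s,stage`).
#' @param png_path optional output PNG (skipped, with a message, when the
#'   graphics device is unavailable).
#' @param colors named stage colour map.
#' @return data.frame `start_s`, `end_s`, `stage`.
#' @export
render_timeline <- function(labels, epoch_s, csv_path = NULL, png_path = NULL,
                            colors = c(wake = "#E5B800", light = "#6BAED6", deep = "#2C3E80")) {
  if (length(labels) == 0) stop_input("labels must be non-empty")
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths) * epoch_s
  out <- data.frame(start_s = c(0, ends[-length(ends)]), end_s = ends, stage = r$values)
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    ok <- tryCatch({
      grDevices::png(png_path, width = 900, height = 220)
      on.exit(grDevices::dev.off(), add = TRUE)
      lv <- unique(out$stage)
      yl <- stats::setNames(seq_along(lv), lv)
      graphics::plot(NULL, xlim = c(0, max(out$end_s)), ylim = c(0.5, length(lv) + 0.5),
                     xlab = "time (s)", ylab = "", yaxt = "n", main = "hypnogram")
      graphics::axis(2, at = yl, labels = names(yl), las = 1)
      for (i in seq_len(nrow(out)))
        graphics::rect(out$start_s[i], yl[out$stage[i]] - 0.35, out$end_s[i],
                       yl[out$stage[i]] + 0.35,
                       col = colors[out$stage[i]] %||% "grey", border = NA)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) message("PNG device unavailable; skipped ", png_path)
  }
  out
}

#' Expand a rendered timeline back to per-epoch labels
#' @param timeline data.frame from [render_timeline()] (or its CSV).
#' @param epoch_s epoch length, seconds.
#' @export
parse_timeline <- function(timeline, epoch_s) {
  if (is.character(timeline)) timeline <- utils::read.csv(timeline)
  unlist(lapply(seq_len(nrow(timeline)), function(i)
    rep(timeline$stage[i], round((timeline$end_s[i] - timeline$start_s[i]) / epoch_s))))
}

#' Aggregate energy accounting over a set of reservoir runs
#'
#' Sums the per-frame write/read energies recorded by [run_reservoir()] and
#' reports joules per inference window and mean power; flags a configuration
#' whose mean read power exceeds 1 nW.
#'
#' @param states list of `fibrc_state_vector`s from [run_reservoir()].
#' @param v_read read voltage used for the read-power figure, volts.
#' @return list with `total_energy_j`, `energy_per_inference_j`,
#'   `mean_power_w`, `mean_read_power_w` and `read_power_ok`.
#' @export
energy_report <- function(states, v_read = 1.0) {
  if (inherits(states, "fibrc_state_vector")) states <- list(states)
  fe <- lapply(states, attr, "frame_energy")
  if (any(vapply(fe, is.null, logical(1))))
    stop_input("states lack frame energies; run them through run_reservoir()")
  total <- sum(unlist(fe))
  drive_time <- sum(vapply(states, function(s)
    attr(s, "frame_duration") * length(s), numeric(1)))
  read_power <- v_read * mean(unlist(lapply(states, as.numeric)))
  list(total_energy_j = total,
       energy_per_inference_j = total / length(states),
       mean_power_w = if (drive_time > 0) total / drive_time else 0,
       mean_read_power_w = read_power,
       read_power_ok = read_power < 1e-9)
}

# ---- task runners -----------------------------------------------------------

# encode one EEG epoch into a state vector
.encode_eeg <- function(epoch, cfg, rcfg) {
  fm <- mtf_transform(epoch, cfg$encoder$n_bins, cfg$encoder$out_size)
  rows <- matrix_to_pulserows(fm, cfg$encoder$mode, cfg$reservoir$frame_k,
                              v_write = rcfg$device_params$v_write,
                              slot_duration = rcfg$device_params$slot_duration,
                              slot_gap = rcfg$device_params$slot_gap)
  run_reservoir(rows, rcfg, modality = "eeg")
}

# encode one audio clip: MFCC, block-average the time axis to audio_cols
.encode_audio <- function(clip, cfg, rcfg) {
  fm <- mfcc_transform(clip, cfg$encoder$n_mfcc, cfg$encoder$frame_len,
                       cfg$encoder$hop, cfg$encoder$n_mels)
  v <- fm$values
  if (ncol(v) > cfg$encoder$audio_cols)
    v <- block_average(v, nrow(v), cfg$encoder$audio_cols)
  rows <- matrix_to_pulserows(v, cfg$encoder$mode, cfg$reservoir$frame_k,
                              v_write = rcfg$device_params$v_write,
                              slot_duration = rcfg$device_params$slot_duration,
                              slot_gap = rcfg$device_params$slot_gap)
  run_reservoir(rows, rcfg, modality = "audio")
}

.gen_task_data <- function(cfg, task, rcfg) {
  n <- cfg$data$n_per_class
  seed <- cfg$seed
  if (task == "stage3") {
    stages <- c("wake", "light", "deep")
    states <- list(); labels <- character(0); raw_fm <- list()
    for (st in stages) for (i in seq_len(n)) {
      ep <- gen_eeg_epoch(st, cfg$data$fs_eeg, cfg$data$epoch_s,
                          seed = substream_seed(seed, paste0("stage3-", st, "-", i)))
      states[[length(states) + 1L]] <- .encode_eeg(ep, cfg, rcfg)
      raw_fm[[length(raw_fm) + 1L]] <- as.numeric(mtf_transform(ep, cfg$encoder$n_bins,
                                                                cfg$encoder$out_size)$values)
      labels <- c(labels, st)
    }
    list(states = states, labels = labels, mode = "stage3", raw = do.call(rbind, raw_fm))
  } else if (task == "snore2") {
    states <- list(); labels <- character(0)
    for (sn in c(TRUE, FALSE)) for (i in seq_len(n)) {
      clip <- gen_snore_clip(cfg$data$clip_s, cfg$data$fs_audio, snore = sn,
                             seed = substream_seed(seed, paste0("snore2-", sn, "-", i)))
      if (cfg$data$ambient != "none")
        clip <- add_ambient(clip, cfg$data$ambient, cfg$data$snr_db,
                            seed = substream_seed(seed, paste0("amb-", sn, "-", i)))
      states[[length(states) + 1L]] <- .encode_audio(clip, cfg, rcfg)
      labels <- c(labels, if (sn) "snore" else "no_snore")
    }
    list(states = states, labels = labels, mode = "snore2")
  } else if (task == "joint6") {
    states <- list(); labels <- character(0)
    for (st in c("wake", "light", "deep")) for (sn in c(TRUE, FALSE)) for (i in seq_len(n)) {
      ep <- gen_eeg_epoch(st, cfg$data$fs_eeg, cfg$data$epoch_s,
                          seed = substream_seed(seed, paste0("j6-eeg-", st, sn, "-", i)))
      clip <- gen_snore_clip(cfg$data$clip_s, cfg$data$fs_audio, snore = sn,
                             seed = substream_seed(seed, paste0("j6-aud-", st, sn, "-", i)))
      if (cfg$data$ambient != "none")
        clip <- add_ambient(clip, cfg$data$ambient, cfg$data$snr_db,
                            seed = substream_seed(seed, paste0("j6-amb-", st, sn, "-", i)))
      s <- fuse_modalities(.encode_eeg(ep, cfg, rcfg), .encode_audio(clip, cfg, rcfg))
      states[[length(states) + 1L]] <- s
      labels <- c(labels, paste0(st, "_", if (sn) "snore" else "no_snore"))
    }
    list(states = states, labels = labels, mode = "joint6")
  } else stop_config("unknown task: ", task)
}

#' Run an end-to-end pipeline task
#'
#' Tasks `"stage3"`, `"snore2"` and `"joint6"` generate synthetic labelled
#' data, encode it (MTF for EEG, MFCC for audio), drive the reservoir, train
#' the configured readout(s) on a stratified split, and evaluate on the
#' held-out windows. Task `"image_demo"` runs the glyph compression
#' round trip. When `cfg$out_dir` is set, a report JSON, confusion CSV,
#' state CSV and manifest are written there.
#'
#' @param cfg a `fibrc_run_config`.
#' @param task one of "stage3", "snore2", "joint6", "image_demo".
#' @return for classification tasks, a list with `report` (per readout kind:
#'   evaluation metrics), `models`, `quantized`, `silhouette`, `energy` and
#'   `data_sizes`; for `image_demo`, the compression results per glyph.
#' @export
run_pipeline <- function(cfg = run_config(), task = c("stage3", "snore2", "joint6", "image_demo")) {
  task <- match.arg(task)
  rcfg <- .cfg_reservoir(cfg)
  t0 <- Sys.time()
  if (task == "image_demo") {
    glyphs <- gen_glyphs(seed = cfg$seed)
    rcfg_img <- reservoir_config(frame_k = cfg$reservoir$frame_k,
                                 device_params = .cfg_device(cfg), mode = "binary")
    res <- lapply(glyphs, compress_image, cfg = rcfg_img)
    exact <- vapply(names(glyphs), function(g)
      identical(res[[g]]$reconstruction, unname(glyphs[[g]])), logical(1))
    out <- list(task = task, results = res, exact = exact)
    if (!is.null(cfg$out_dir)) .write_artifacts_image(out, cfg)
    return(out)
  }
  dat <- .gen_task_data(cfg, task, rcfg)
  ls_all <- labeled_states(dat$states, dat$labels, dat$mode)
  split <- stratified_split(ls_all, cfg$readout$split,
                            seed = substream_seed(cfg$seed, "split"))
  kinds <- if (cfg$readout$kind == "both") c("linear", "cnn") else cfg$readout$kind
  models <- list(); report <- list(); quantized <- list()
  for (k in kinds) {
    m <- if (k == "linear") train_linear(split$train, l2 = cfg$readout$l2)
    else train_cnn(split$train, epochs = cfg$readout$epochs, lr = cfg$readout$lr,
                   momentum = cfg$readout$momentum, seed = substream_seed(cfg$seed, "cnn"))
    pr <- predict(m, split$val)
    report[[k]] <- evaluate(as.character(split$val$y), pr$labels, levels(split$val$y))
    models[[k]] <- m
    q <- quantize_weights(m, 16, eval_data = split$val)
    quantized[[k]] <- list(accuracy_before = q$accuracy_before,
                           accuracy_after = q$accuracy_after,
                           accuracy_delta = q$accuracy_delta)
  }
  proj <- project_states(ls_all, 2)
  sil <- silhouette_score(proj$scores, dat$labels)
  en <- energy_report(dat$states, v_read = rcfg$device_params$v_read)
  out <- list(task = task, report = report, models = models, quantized = quantized,
              silhouette = sil, energy = en,
              data_sizes = c(train = nrow(split$train$X), val = nrow(split$val$X)),
              runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
              seed = cfg$seed)
  if (task == "stage3") out$silhouette_raw <- silhouette_score(project_states(dat$raw, 2)$scores, dat$labels)
  if (!is.null(cfg$out_dir)) .write_artifacts(out, cfg, ls_all, split, dat)
  out
}

# polynomial rolling hash of the serialised config, for the manifest
.config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647
  sprintf("%08x", h)
}

.write_artifacts <- function(out, cfg, ls_all, split, dat) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  rep_json <- list(task = out$task, seed = out$seed, silhouette = out$silhouette,
                   energy = out$energy, data_sizes = as.list(out$data_sizes),
                   quantized = out$quantized,
                   accuracy = lapply(out$report, `[[`, "accuracy"))
  jsonlite::write_json(rep_json, file.path(cfg$out_dir, paste0(out$task, "_report.json")),
                       auto_unbox = TRUE, digits = NA)
  for (k in names(out$report))
    utils::write.csv(out$report[[k]]$confusion,
                     file.path(cfg$out_dir, paste0(out$task, "_confusion_", k, ".csv")))
  write_states_csv(dat$states, file.path(cfg$out_dir, paste0(out$task, "_states.csv")),
                   labels = dat$labels)
  if ("linear" %in% names(out$models) && nrow(split$val$X) > 0) {
    cm <- cam(out$models$linear, split$val$X[1, , drop = FALSE])
    utils::write.table(cm, file.path(cfg$out_dir, paste0(out$task, "_cam.csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(config_hash = .config_hash(cfg), seed = cfg$seed,
                            r_version = as.character(getRversion()),
                            package_version = as.character(utils::packageVersion("fibrc")),
                            timestamp = format(Sys.time(), tz = "UTC")),
                       file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(NULL)
}

.write_artifacts_image <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(out$results)) {
    rec <- out$results[[g]]$reconstruction
    write_pgm(rec, file.path(cfg$out_dir, paste0("glyph_", g, "_reconstruction.pgm")))
    utils::write.table(out$results[[g]]$compressed,
                       file.path(cfg$out_dir, paste0("glyph_", g, "_compressed.csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(exact = as.list(out$exact), config_hash = .config_hash(cfg),
                            seed = cfg$seed),
                       file.path(cfg$out_dir, "image_demo_report.json"), auto_unbox = TRUE)
  invisible(NULL)
}
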