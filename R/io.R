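# Image/mask readers and writers, run configuration, and the command-line
# interface tying the stages together. Coordinate convention throughout:
# row-major matrices, (row, col), 0-based offsets where offsets appear;
# pixel spacing defaults to 1 when no metadata is present (HD95 then in
# pixels).

#' Read a grayscale image
#'
#' Supported formats: PNG and TIFF (any bit depth the readers support) and
#' NIfTI (`.nii` / `.nii.gz`). Multi-channel inputs are converted to
#' grayscale by the Rec. 601 luminance weights. Pixel spacing from NIfTI
#' headers is retained in the `"spacing"` attribute (default `c(1, 1)`).
#'
#' @param path File path.
#' @return Numeric matrix with a `"spacing"` attribute.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("format error: no such file: %s", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  spacing <- c(1, 1)
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("format error: TIFF support requires the tiff package")
      tiff::readTIFF(path)
    },
    nii = {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stopf("format error: NIfTI support requires the RNifti package")
      n <- RNifti::readNifti(path)
      pd <- RNifti::pixdim(n)
      if (length(pd) >= 2) spacing <- pd[1:2]
      a <- as.array(n)
      if (length(dim(a)) > 2) {
        if (all(dim(a)[-(1:2)] == 1)) a <- array(a, dim(a)[1:2])
        else stopf("format error: %s is not a 2D image", path)
      }
      a
    },
    dcm = , dicom = stopf("format error: DICOM reading is not supported: %s",
                          path),
    stopf("format error: unsupported format '%s' for %s", ext, path)
  )
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  img <- matrix(as.numeric(img), nrow(img))
  attr(img, "spacing") <- spacing
  img
}

#' Write a binary mask as a lossless 8-bit PNG (0/255 encoding)
#'
#' @param mask Binary (0/1) matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  if (!is_binary(mask)) stopf("invalid argument: mask must be binary 0/1")
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

# ---- minimal 16-bit grayscale PNG encoder ------------------------------
# png::writePNG only emits 8-bit samples; phantom images are stored at
# 16-bit depth, so the few PNG chunks needed are assembled here directly
# (zlib stream rebuilt from memCompress output, CRC32/Adler32 in R).

crc32_table <- function() {
  .memo("crc32_table", function() {
    vapply(0:255, function(n) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(c, 1))
             else bitwShiftR(c, 1)
      c
    }, integer(1))
  })
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    c <- bitwXor(tab[bitwAnd(bitwXor(c, b[i]), 255L) + 1L], bitwShiftR(c, 8))
  }
  bitwXor(c, -1L)
}

adler32 <- function(bytes) {
  d <- as.numeric(bytes)
  n <- length(d)
  a <- (1 + sum(d)) %% 65521
  bsum <- (n + sum(d * (n - seq_len(n) + 1))) %% 65521
  bsum * 65536 + a
}

u32be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body) %% 2^32
  c(u32be(length(data)), body, u32be(crc))
}

# PNG needs a zlib (RFC 1950) stream; R's memCompress emits exactly that
# (0x78 header). If a build ever returns a gzip wrapper instead, the
# deflate payload is rewrapped with an Adler-32 checksum.
zlib_compress <- function(bytes) {
  gz <- memCompress(bytes, type = "gzip")
  if (as.integer(gz[1]) == 0x78) return(gz)
  if (as.integer(gz[1]) != 0x1f || as.integer(gz[4]) != 0L)
    stopf("unrecognised compression wrapper")
  deflate <- gz[11:(length(gz) - 8)]
  c(as.raw(c(0x78, 0x9c)), deflate, u32be(adler32(bytes)))
}

#' Write a matrix as a 16-bit grayscale PNG
#'
#' Values are clamped to \[0, 1\] and quantised to 16 bits (65535 levels).
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_png16 <- function(image, path) {
  h <- nrow(image); w <- ncol(image)
  v <- round(pmin(pmax(image, 0), 1) * 65535)
  hi <- as.raw(t(v) %/% 256)
  lo <- as.raw(t(v) %% 256)
  samples <- as.vector(rbind(as.integer(hi), as.integer(lo)))
  scan <- matrix(samples, nrow = 2 * w)          # one column per image row
  raw_rows <- rbind(0L, scan)                    # filter byte 0 per scanline
  payload <- as.raw(as.vector(raw_rows))
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_compress(payload)),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

# ---- run configuration -------------------------------------------------

default_run_config <- function() {
  list(
    synth = list(height = 64, width = 64, n = 10, n_lesions = 1,
                 contrast = 3, radius_min = 4, radius_max = 10,
                 boundary_sigma = 1.5, texture_scale = 12, seed = 1),
    preprocess = list(size = 256, clip = 5),
    train = list(epochs = 300, learning_rate = 0.000015625, batch_size = 4,
                 duplication = 2, alpha = 0.5, patience = 20, seed = 1,
                 n_hidden = 16, hidden_width = 32, n_levels = 2,
                 steps_coarse = 10, steps_fine = 10, sgb = 1,
                 fire_rate = 0.5, val_every = 1, augment = 1),
    predict = list(n_e = 1, threshold = 0.5, seed = 1),
    evaluate = list(),
    qa = list(runs = 10, flag_threshold = 0.5, seed = 1)
  )
}

#' Read and validate a run configuration
#'
#' YAML configuration mirroring the CLI stages; unknown keys are rejected.
#'
#' @param path YAML file path (or `NULL` for the defaults).
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, "")
}

merge_config <- function(base, user, prefix) {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stopf("config error: unknown key '%s%s'", prefix, nm)
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(prefix, nm, "."))
    else base[[nm]] <- user[[nm]]
  }
  base
}

archive_config <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(dir, "run_config.yaml"))
}

# ---- command-line interface --------------------------------------------

cli_usage <- function() {
  paste(
    "usage: ncaseg <stage> [--key value ...]",
    "stages:",
    "  synth      --out DIR [--height H --width W --n N --contrast C --seed S]",
    "  preprocess --in DIR --out DIR [--size 256 --clip 5]",
    "  train      --data DIR --out model.ckpt [--config cfg.yaml --epochs E ...]",
    "  predict    --model model.ckpt --in DIR|img.png --out DIR [--n_e K]",
    "  evaluate   --pred DIR --truth DIR --out metrics.csv",
    "  qa         --model model.ckpt --in DIR --out report.csv [--runs 10]",
    "common flags: --config cfg.yaml, --help",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stopf("usage error: expected --flag, got '%s'", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stopf("usage error: flag --%s needs a value", key)
    val <- args[i + 1]
    num <- suppressWarnings(as.numeric(val))
    flags[[key]] <- if (!is.na(num)) num else val
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the `synth`, `preprocess`, `train`, `predict`, `evaluate` and
#' `qa` stages. Flags override values from an optional `--config` YAML file;
#' each stage archives its effective configuration beside its outputs and is
#' re-runnable from that archive with identical results (fixed seeds).
#'
#' @param argv Character vector of arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code: 0 on success, 1 on stage failure, 2 on usage
#'   errors.
#' @export
main_cli <- function(argv = character()) {
  if (length(argv) == 0 || argv[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  stage <- argv[1]
  stages <- c("synth", "preprocess", "train", "predict", "evaluate", "qa")
  if (!stage %in% stages) {
    message("unknown subcommand: ", stage, "\n", cli_usage())
    return(invisible(2L))
  }
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", cli_usage())
    return(invisible(2L))
  }
  res <- tryCatch({
    cfg <- read_run_config(flags$config)
    flags$config <- NULL
    paths <- flags[names(flags) %in% c("out", "in", "data", "model",
                                       "pred", "truth")]
    opts <- flags[!names(flags) %in% names(paths)]
    cfg[[stage]] <- merge_config(cfg[[stage]], opts, paste0(stage, "."))
    do.call(paste0("cli_", stage), list(cfg = cfg[[stage]], paths = paths))
    0L
  }, error = function(e) {
    message("error in stage '", stage, "': ", conditionMessage(e))
    1L
  })
  invisible(res)
}

cli_synth <- function(cfg, paths) {
  if (is.null(paths$out)) stopf("usage error: synth needs --out")
  spec <- phantom_spec(height = cfg$height, width = cfg$width,
                       n_lesions = cfg$n_lesions,
                       radius_range = c(cfg$radius_min, cfg$radius_max),
                       contrast = cfg$contrast,
                       boundary_sigma = cfg$boundary_sigma,
                       texture_scale = cfg$texture_scale, seed = cfg$seed)
  ds <- generate_dataset(spec, n = cfg$n, seed = cfg$seed)
  write_phantom_dataset(ds, paths$out)
  archive_config(list(synth = cfg), paths$out)
  message(sprintf("synth: wrote %d phantoms to %s", cfg$n, paths$out))
}

list_pairs <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "_image\\.png$", full.names = TRUE))
  if (!length(imgs)) stopf("no *_image.png files in %s", dir)
  ids <- sub("_image\\.png$", "", basename(imgs))
  masks <- file.path(dir, paste0(ids, "_mask.png"))
  list(ids = ids, images = imgs,
       masks = ifelse(file.exists(masks), masks, NA))
}

cli_preprocess <- function(cfg, paths) {
  if (is.null(paths$`in`) || is.null(paths$out))
    stopf("usage error: preprocess needs --in and --out")
  pr <- list_pairs(paths$`in`)
  dir.create(paths$out, showWarnings = FALSE, recursive = TRUE)
  pc <- preproc_config(target_size = c(cfg$size, cfg$size),
                       clip_bound = cfg$clip)
  for (i in seq_along(pr$ids)) {
    im <- preprocess_image(read_image(pr$images[i]), pc)
    write_png16(im, file.path(paths$out, paste0(pr$ids[i], "_image.png")))
    if (!is.na(pr$masks[i])) {
      m <- resize_image(read_image(pr$masks[i]), pc$target_size, "nearest")
      write_mask((m != 0) * 1, file.path(paths$out,
                                         paste0(pr$ids[i], "_mask.png")))
    }
  }
  archive_config(list(preprocess = cfg), paths$out)
  message(sprintf("preprocess: %d images -> %s", length(pr$ids), paths$out))
}

cli_train <- function(cfg, paths) {
  if (is.null(paths$data) || is.null(paths$out))
    stopf("usage error: train needs --data and --out")
  pr <- list_pairs(paths$data)
  if (anyNA(pr$masks)) stopf("train: masks missing in %s", paths$data)
  imgs <- lapply(pr$images, read_image)
  masks <- lapply(pr$masks, function(p) (read_image(p) != 0) * 1)
  mc <- model_config(n_hidden = cfg$n_hidden, hidden_width = cfg$hidden_width,
                     fire_rate = cfg$fire_rate, n_levels = cfg$n_levels,
                     steps_coarse = cfg$steps_coarse,
                     steps_fine = cfg$steps_fine, use_sgb = cfg$sgb > 0,
                     seed = cfg$seed)
  tc <- train_config(learning_rate = cfg$learning_rate,
                     max_epochs = cfg$epochs,
                     early_stop_patience = cfg$patience,
                     batch_size = cfg$batch_size, duplication = cfg$duplication,
                     alpha = cfg$alpha, seed = cfg$seed,
                     val_every = cfg$val_every, augment = cfg$augment > 0)
  fit <- ncaseg(imgs, masks, model = mc, train = tc)
  save_ncaseg(fit$model, paths$out)
  utils::write.csv(fit$history, paste0(paths$out, "_history.csv"),
                   row.names = FALSE)
  archive_config(list(train = cfg), dirname(paths$out))
  message(sprintf("train: %d epochs, final train dice %.3f -> %s",
                  nrow(fit$history),
                  fit$history$train_dice[nrow(fit$history)], paths$out))
}

cli_predict <- function(cfg, paths) {
  if (is.null(paths$model) || is.null(paths$`in`) || is.null(paths$out))
    stopf("usage error: predict needs --model, --in and --out")
  model <- load_ncaseg(paths$model)
  files <- if (dir.exists(paths$`in`)) list_pairs(paths$`in`)$images
           else paths$`in`
  ids <- sub("_image\\.png$|\\.png$", "", basename(files))
  dir.create(paths$out, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(files)) {
    img <- rescale_unit(clip_outliers(zscore_normalize(read_image(files[i])),
                                      5))
    p <- if (cfg$n_e > 1)
      pseudo_ensemble(model, img, cfg$n_e, seed = cfg$seed,
                      preprocess = FALSE)$mean_prob
    else with_seed(cfg$seed, forward_batch(model, list(img))[[1]])
    write_mask((p >= cfg$threshold) * 1,
               file.path(paths$out, paste0(ids[i], "_pred.png")))
    write_png16(p, file.path(paths$out, paste0(ids[i], "_prob.png")))
  }
  archive_config(list(predict = cfg), paths$out)
  message(sprintf("predict: %d images -> %s", length(files), paths$out))
}

cli_evaluate <- function(cfg, paths) {
  if (is.null(paths$pred) || is.null(paths$truth) || is.null(paths$out))
    stopf("usage error: evaluate needs --pred, --truth and --out")
  preds <- sort(list.files(paths$pred, pattern = "_pred\\.png$",
                           full.names = TRUE))
  if (!length(preds)) stopf("no *_pred.png files in %s", paths$pred)
  ids <- sub("_pred\\.png$", "", basename(preds))
  rows <- lapply(seq_along(ids), function(i) {
    g <- (read_image(file.path(paths$truth,
                               paste0(ids[i], "_mask.png"))) != 0) * 1
    p <- (read_image(preds[i]) != 0) * 1
    hd <- tryCatch(hd95(p, g), error = function(e) NA_real_)
    data.frame(id = ids[i], acc = pixel_accuracy(p, g),
               dice = dice_coefficient(p, g), miou = miou(p, g), hd95 = hd)
  })
  tab <- do.call(rbind, rows)
  m <- data.frame(id = "mean_sd",
                  acc = sprintf("%.4f +/- %.4f", mean(tab$acc), stats::sd(tab$acc)),
                  dice = sprintf("%.4f +/- %.4f", mean(tab$dice), stats::sd(tab$dice)),
                  miou = sprintf("%.4f +/- %.4f", mean(tab$miou), stats::sd(tab$miou)),
                  hd95 = sprintf("%.4f +/- %.4f", mean(tab$hd95, na.rm = TRUE),
                                 stats::sd(tab$hd95, na.rm = TRUE)))
  out <- rbind(data.frame(lapply(tab, as.character)), m)
  utils::write.csv(out, paths$out, row.names = FALSE)
  message(sprintf("evaluate: mean dice %.4f over %d images -> %s",
                  mean(tab$dice), nrow(tab), paths$out))
}

cli_qa <- function(cfg, paths) {
  if (is.null(paths$model) || is.null(paths$`in`) || is.null(paths$out))
    stopf("usage error: qa needs --model, --in and --out")
  model <- load_ncaseg(paths$model)
  pr <- list_pairs(paths$`in`)
  imgs <- lapply(pr$images, function(p)
    rescale_unit(clip_outliers(zscore_normalize(read_image(p)), 5)))
  rep <- qa_report(model, imgs, n_e = cfg$runs,
                   flag_threshold = cfg$flag_threshold, seed = cfg$seed)
  rep$id <- pr$ids
  utils::write.csv(rep, paths$out, row.names = FALSE)
  message(sprintf("qa: %d images, median nqm %.4f -> %s",
                  nrow(rep), stats::median(rep$nqm, na.rm = TRUE), paths$out))
}
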