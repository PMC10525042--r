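#' Run the CSF curve pipeline from a config
#'
#' Reproducible end-to-end run: load or simulate an object set, compute the
#' empirical CSF curve, select K by the one-SD rule (and by the
#' uniform-reference log-ratio when `reference: true`), and write
#' `curve.json`, `curve.csv` and `selection.json` into the output
#' directory. Every artifact embeds the seed and a hash of the config, so
#' reruns with an identical config are byte-identical.
#'
#' Config keys (list or YAML/JSON path): `input` (either
#' `list(kind = "strings_csv", path = ...)` with columns `id,value`, or
#' `list(kind = "simulate", n_classes = ..., per_class = ..., length = ...,
#' noise_rate = ...)`), `compressor` (`name`, `options`), `k_max`,
#' `n_subsamples`, `seed`, `reference` (logical), `out_dir`.
#'
#' @param config A named list or path to a YAML/JSON config file.
#' @return Invisibly, a list with `curve`, `selection`, `paths`.
#' @export
run_curve <- function(config) {
  cfg <- load_config(config, required = c("out_dir"))
  seed <- as.integer(cfg$seed %||% 1L)
  k_max <- as.integer(cfg$k_max %||% 5L)
  n_subsamples <- as.integer(cfg$n_subsamples %||% 100L)
  spec <- compressor_spec(cfg$compressor$name %||% "gzip",
                          cfg$compressor$options %||% list())
  set <- load_object_set(cfg$input, seed)
  curve <- csf_empirical(set, k_max, spec, n_subsamples = n_subsamples,
                         seed = seed)
  sel <- select_one_sd(curve)
  selections <- list(one_sd = list(chosen_k = sel$chosen_k))
  if (isTRUE(cfg$reference)) {
    ref <- uniform_reference(set, seed = seed + 1000L)
    curve_n <- csf_empirical(ref, k_max, spec, n_subsamples = n_subsamples,
                             seed = seed)
    lr <- select_log_ratio(curve, curve_n)
    selections$log_ratio <- list(chosen_k = lr$chosen_k,
                                 d = lr$diagnostics$d)
  }
  meta <- list(seed = seed,
               config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(curve_json = file.path(cfg$out_dir, "curve.json"),
                curve_csv = file.path(cfg$out_dir, "curve.csv"),
                selection_json = file.path(cfg$out_dir, "selection.json"))
  jsonlite::write_json(c(meta, list(curve = tidy(curve))),
                       paths$curve_json, auto_unbox = TRUE, digits = NA)
  utils::write.csv(tidy(curve), paths$curve_csv, row.names = FALSE)
  jsonlite::write_json(c(meta, selections), paths$selection_json,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(curve = curve, selection = sel, paths = paths))
}

#' Run the ensemble segmentation pipeline from a config
#'
#' Loads an intensity image and candidate label masks (one 16-bit TIFF per
#' radius setting), scores and combines them ([select_ensemble()]), and
#' writes the final non-overlapping label mask (`final_mask.tif`) plus a
#' per-bucket JSON report.
#'
#' Config keys: `image` (grayscale TIFF/PNG path), `candidates` (named
#' list or vector of mask paths; names taken as radius annotations),
#' `out_dir`, optional `threshold` (`window`, `offset`), `seed`.
#'
#' @param config A named list or path to a YAML/JSON config file.
#' @return Invisibly, a list with `selection` and `paths`.
#' @export
run_ensemble <- function(config) {
  cfg <- load_config(config, required = c("image", "candidates", "out_dir"))
  img <- read_intensity_image(cfg$image)
  masks <- cfg$candidates
  cand <- purrr::imap(as.list(masks), function(path, nm) {
    m <- read_label_mask(path)
    if (!all(dim(m) == dim(img))) {
      stop(sprintf("mask '%s' shape does not match the image", path),
           call. = FALSE)
    }
    r <- suppressWarnings(as.numeric(nm))
    mask_to_candidates(m, radius = if (length(r) && !is.na(r)) r
                                   else NA_real_)
  }) |> purrr::list_rbind()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(mask = file.path(cfg$out_dir, "final_mask.tif"),
                report = file.path(cfg$out_dir, "selection.json"))
  meta <- list(seed = as.integer(cfg$seed %||% 1L),
               config_hash = rlang::hash(cfg[setdiff(names(cfg),
                                                     "out_dir")]))
  if (nrow(cand) == 0L) {
    warning("no candidate regions found; writing an empty mask",
            call. = FALSE)
    write_label_mask(matrix(0L, nrow(img), ncol(img)), paths$mask)
    jsonlite::write_json(c(meta, list(buckets = list())), paths$report,
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(selection = NULL, paths = paths)))
  }
  cand$id <- seq_len(nrow(cand))
  thr <- adaptive_threshold(img,
                            window = as.integer(cfg$threshold$window %||%
                                                  31L),
                            offset = cfg$threshold$offset %||% 0.4)
  selection <- select_ensemble(cand, img, threshold = thr)
  write_label_mask(selection$mask, paths$mask)
  buckets <- selection$candidates |>
    dplyr::group_by(.data$bucket) |>
    dplyr::summarise(members = list(.data$id), scores = list(.data$score),
                     .groups = "drop")
  buckets$chosen <- lapply(buckets$bucket, function(b)
    selection$selected$id[selection$selected$bucket == b])
  jsonlite::write_json(
    c(meta, list(buckets = buckets, n_selected = nrow(selection$selected))),
    paths$report, auto_unbox = TRUE, digits = NA)
  invisible(list(selection = selection, paths = paths))
}

load_config <- function(config, required = character(0)) {
  cfg <- if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a list or a YAML/JSON path", call. = FALSE)
  }
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing required keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg
}

load_object_set <- function(input, seed) {
  if (is.null(input)) stop("config is missing `input`", call. = FALSE)
  kind <- input$kind %||% "strings_csv"
  if (kind == "strings_csv") {
    if (is.null(input$path) || !file.exists(input$path)) {
      stop("input file not found: ", input$path %||% "<missing>",
           call. = FALSE)
    }
    d <- utils::read.csv(input$path, stringsAsFactors = FALSE)
    if (!all(c("id", "value") %in% names(d))) {
      stop("strings_csv input needs `id` and `value` columns",
           call. = FALSE)
    }
    object_set(as.list(d$value), ids = d$id,
               labels = d$label %||% NULL)
  } else if (kind == "simulate") {
    template_class_strings(n_classes = as.integer(input$n_classes %||% 2L),
                           per_class = as.integer(input$per_class %||% 50L),
                           length = as.integer(input$length %||% 1000L),
                           noise_rate = input$noise_rate %||% 0.02,
                           seed = seed)
  } else {
    stop("unknown input kind: ", kind, call. = FALSE)
  }
}

read_intensity_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1] # first channel
  img <- img - min(img)
  if (max(img) > 0) img <- img / max(img)
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a
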