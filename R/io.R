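# Formats, configuration and the end-to-end evaluation pipeline.

#' Read / write 8-bit grayscale images
#'
#' PNG via the png package; TIFF via the tiff package when installed.
#' Images are integer matrices with values 0..255.
#'
#' @param path File path.
#' @param img Integer matrix in `[0, 255]`.
#' @return `read_image8` returns the integer matrix; `write_image8` its path,
#'   invisibly.
#' @export
read_image8 <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("png")) {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else abort(sprintf("unsupported image format: '%s'", path))
  if (length(dim(a)) == 3) {
    if (dim(a)[3] > 1 && !all(a[, , 1] == a[, , 2]))
      abort(sprintf("'%s' is not a grayscale image", basename(path)))
    a <- a[, , 1]
  }
  v <- a * 255
  if (max(abs(v - round(v))) > 1e-6)
    abort(sprintf("'%s' is not an 8-bit image", basename(path)))
  m <- round(v)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_image8
#' @export
write_image8 <- function(img, path) {
  stopifnot_image8(img)
  ok <- tryCatch({
    png::writePNG(img / 255, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("failed to write image '%s'", path))
  invisible(path)
}

#' Read an image ensemble from a directory
#'
#' Loads all PNG/TIFF files in deterministic lexicographic (C-locale) order,
#' validating that every image is 8-bit grayscale and that all share one
#' size; a `manifest.csv` (if present) is joined by filename.
#'
#' @param dir Directory of 8-bit grayscale images.
#' @return A `dgm_ensemble` with `images` and `manifest`.
#' @export
read_ensemble <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("directory '%s' does not exist", dir))
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  files <- files[order(files, method = "radix")]
  if (!length(files)) abort(sprintf("no PNG/TIFF images found in '%s'", dir))
  imgs <- lapply(files, function(f) read_image8(file.path(dir, f)))
  sizes <- vapply(imgs, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(sizes)) > 1) {
    main <- names(which.max(table(sizes)))
    abort(sprintf("mixed image sizes; offenders: %s",
                  paste(files[sizes != main], collapse = ", ")))
  }
  names(imgs) <- files
  manifest <- tibble(filename = files)
  mpath <- file.path(dir, "manifest.csv")
  if (file.exists(mpath)) {
    mf <- as_tibble(utils::read.csv(mpath, stringsAsFactors = FALSE))
    manifest <- dplyr::left_join(manifest, mf, by = "filename")
  }
  structure(list(manifest = manifest, images = imgs, layouts = NULL,
                 config = list(image_size = nrow(imgs[[1]]),
                               n_images = length(imgs))),
            class = "dgm_ensemble")
}

#' Evaluation run configuration
#'
#' Bundles every tunable of the pipeline with its default; unknown keys are
#' rejected. The configuration is serialised alongside every report.
#'
#' @param train_dir,gen_dir Ensemble directories (may be `NULL` when
#'   ensembles are passed directly to [run_full_evaluation()]).
#' @param ... Overrides of the defaults listed below.
#' @return Named list of class `dgm_run_config`.
#' @export
run_config <- function(train_dir = NULL, gen_dir = NULL, ...) {
  cfg <- list(train_dir = train_dir, gen_dir = gen_dir,
              out = NULL, cache = NULL,
              seed = 1L,
              fid_threshold = 30,
              fid_embedder = "feature-registry",
              mem_threshold = 0.9,
              mem_radius = 2,
              mem_candidates = 50,
              n_pcs = 10, n_pairs = 10000, n_boot = 1000,
              k_density = 5,
              lag_max = 100,
              families = TRUE,
              skin_band_width = 4)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "dgm_run_config")
}

#' @describeIn run_config Read a configuration from a YAML or JSON file
#'   (keys as in `run_config()`; unknown keys rejected).
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else abort("config file must be .yaml, .yml or .json")
  do.call(run_config, vals)
}

#' Run the full two-stage evaluation
#'
#' Stage 1 (advisory screen): Frechet distance between embeddings with a
#' pass/fail at `fid_threshold`, and memorization flags at `mem_threshold`.
#' Stage 2: the bootstrapped KS ranking metric (with per-family sub-metrics
#' when `families`). Diagnostics: class prevalence, per-class density and
#' coverage in the top-2 PC space, ensemble-mean semivariance of both
#' ensembles, and the artifact scan. Failures in one stage are recorded and
#' later independent stages still run. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param train,gen Optional ensembles / feature tables overriding the
#'   configured directories. Feature tables are computed (and cached as CSV
#'   under `config$cache`) when not supplied.
#' @param train_features,gen_features Optional precomputed feature tables.
#' @return Object of class `dgm_eval_report` (self-contained list; see
#'   [write_eval_report()]).
#' @export
run_full_evaluation <- function(config = run_config(), train = NULL,
                                gen = NULL, train_features = NULL,
                                gen_features = NULL) {
  thresholds <- segmentation_thresholds(skin_band_width = config$skin_band_width)
  train <- train %||% read_ensemble(config$train_dir)
  gen <- gen %||% read_ensemble(config$gen_dir)
  errors <- list()
  note <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  cache_or_extract <- function(ens, tag) {
    cache_file <- if (!is.null(config$cache))
      file.path(config$cache, paste0(tag, "_features.csv"))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      tab <- read_feature_cache(cache_file)
      if (!is.null(tab)) return(tab)
    }
    tab <- feature_table(ens, thresholds)
    if (!is.null(cache_file)) {
      dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
      write_feature_cache(tab, cache_file)
    }
    tab
  }
  ft <- train_features %||% cache_or_extract(train, "train")
  fg <- gen_features %||% cache_or_extract(gen, "gen")

  stage1 <- tryCatch({
    emb_t <- embed_ensemble(if (config$fid_embedder == "feature-registry") ft
                            else train,
                            method = config$fid_embedder, seed = config$seed)
    emb_g <- embed_ensemble(if (config$fid_embedder == "feature-registry") fg
                            else gen,
                            method = config$fid_embedder, seed = config$seed)
    # registry features live on wildly different scales; standardise both
    # sides with training statistics so the distance is scale-free
    if (config$fid_embedder == "feature-registry") {
      mu <- colMeans(emb_t)
      sc <- apply(emb_t, 2, stats::sd)
      keep <- is.finite(sc) & sc > 0
      emb_t <- sweep(sweep(emb_t[, keep, drop = FALSE], 2, mu[keep]), 2,
                     sc[keep], "/")
      emb_g <- sweep(sweep(emb_g[, keep, drop = FALSE], 2, mu[keep]), 2,
                     sc[keep], "/")
    }
    fid <- frechet_distance(emb_t, emb_g)
    mem <- memorization_measure(gen, train, radius = config$mem_radius,
                                threshold = config$mem_threshold,
                                n_candidates = config$mem_candidates,
                                thresholds = thresholds)
    list(fid = fid, fid_pass = fid <= config$fid_threshold,
         fid_threshold = config$fid_threshold,
         n_memorized = sum(mem$report$flagged),
         mem_threshold = config$mem_threshold,
         max_memorization = max(mem$report$measure))
  }, error = function(e) note("stage1", e))

  stage2 <- tryCatch({
    rk <- ranking_metric(ft, fg, n_pcs = config$n_pcs,
                         n_pairs = config$n_pairs, n_boot = config$n_boot,
                         seed = config$seed, families = config$families)
    list(mean_ks = rk$mean_ks, sd_ks = rk$sd_ks,
         per_family = if (!is.null(rk$per_family))
           as.data.frame(rk$per_family))
  }, error = function(e) note("stage2", e))

  diagnostics <- tryCatch({
    model2 <- fit_pc_space(ft, n_components = 2)
    st <- project_pc(model2, ft, 2)
    sg <- project_pc(model2, fg, 2)
    cls_of <- function(ens) {
      if (!is.null(ens$manifest$class)) return(ens$manifest$class)
      vapply(ensemble_images(ens), function(im)
        tryCatch(classify_by_glandularity(segment_tissues(im, thresholds)),
                 error = function(e) NA_character_), character(1))
    }
    ct <- cls_of(train); cg <- cls_of(gen)
    dc <- density_coverage(st, sg, k = config$k_density,
                           train_class = ct, gen_class = cg)
    sv_gen <- mean_image_semivariance(gen, lag_max = config$lag_max,
                                      seed = config$seed)
    art <- artifact_scan(gen, train_reference = NULL,
                         thresholds = thresholds, seed = config$seed)
    list(prevalence = as.list(table(factor(cg, BREAST_CLASSES)) / length(cg)),
         density_coverage = as.data.frame(dc),
         semivariance_sill = sv_gen$sill,
         semivariance_rel_slope = sv_gen$rel_slope,
         artifacts = as.data.frame(glance(art)))
  }, error = function(e) note("diagnostics", e))

  structure(list(schema_version = "1.0",
                 registry_version = registry_version(),
                 config = unclass(config),
                 stage1 = stage1, stage2 = stage2,
                 diagnostics = diagnostics,
                 errors = errors),
            class = "dgm_eval_report")
}

#' Write / read an evaluation report as JSON
#'
#' The report round-trips through its own reader; every number is traceable
#' to the embedded config snapshot.
#'
#' @param report A `dgm_eval_report`.
#' @param path JSON file path.
#' @return `write_eval_report` returns the path invisibly;
#'   `read_eval_report` the report list.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "dgm_eval_report"
  rep
}

#' @export
print.dgm_eval_report <- function(x, ...) {
  cat("<dgm_eval_report>\n")
  if (!is.null(x$stage1))
    cat(sprintf("  stage 1: FID %.2f (%s), %d memorized\n", x$stage1$fid,
                if (isTRUE(x$stage1$fid_pass)) "pass" else "FAIL",
                x$stage1$n_memorized))
  if (!is.null(x$stage2))
    cat(sprintf("  stage 2: mean KS %.4f (sd %.4f)\n",
                x$stage2$mean_ks, x$stage2$sd_ks))
  if (length(x$errors))
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

# Feature-table CSV cache with the registry version stamped in a header
# comment; a version mismatch invalidates the cache.
write_feature_cache <- function(tab, path) {
  con <- file(path, "w")
  writeLines(paste0("# registry_version: ", registry_version()), con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  invisible(path)
}

read_feature_cache <- function(path) {
  first <- readLines(path, n = 1)
  ver <- sub("^# registry_version: ", "", first)
  if (!identical(ver, registry_version())) return(NULL)
  tab <- as_tibble(utils::read.csv(path, comment.char = "#",
                                   stringsAsFactors = FALSE))
  attr(tab, "registry_version") <- ver
  tab
}
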