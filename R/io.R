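# Readers/writers for images, masks, measurements, and configuration.

#' Read and write 8-bit PNG images and masks
#'
#' Images are grayscale PNGs with values mapped to `[0, 1]`; masks use
#' foreground 255 / background 0. Multi-channel PNGs are averaged to
#' grayscale on read for images and rejected for masks.
#'
#' @param path File path.
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param mask Binary matrix.
#' @return Readers return a matrix; writers the path, invisibly.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read image '%s'", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  a
}

#' @rdname read_image_png
#' @export
write_image_png <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels, 0), 1), path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read mask '%s'", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) abort(sprintf("mask '%s' must be single-channel", path))
  m <- matrix(as.integer(a >= 0.5), nrow(a), ncol(a))
  m
}

#' @rdname read_image_png
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Serialize a measurement to JSON
#'
#' Schema: `biomarker`, `p1`/`p2` as `[row, col]` (1-based pixel
#' coordinates), `length_px`, `length_mm`, `spacing_mm_per_px`, `warnings`.
#'
#' @param m A `renal_measurement`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly if `path` given).
#' @export
measurement_to_json <- function(m, path = NULL) {
  obj <- list(biomarker = m$biomarker,
              p1 = round(as.numeric(m$p1), 3),
              p2 = round(as.numeric(m$p2), 3),
              length_px = m$length_px,
              length_mm = m$length_mm,
              spacing_mm_per_px = m$spacing_mm_per_px,
              warnings = as.list(m$warnings))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# --- configuration ---------------------------------------------------------

default_config_bundle <- function() {
  list(network = unclass(network_config()),
       train = unclass(train_config()),
       measure = list(parenchyma_strategy = "maxmin",
                      hilum_side = "auto",
                      threshold = 0.5,
                      crop_margin = 0.1))
}

#' Load (or default) a validated configuration bundle
#'
#' Parses YAML or JSON (by extension), fills every missing field with the
#' package default (batch 32, at most 47 steps, learning rate 1e-4, kernel 5,
#' leaky slope 0.2, dropout 0.5, input 320 x 480 x 1), validates all
#' invariants, and reports every unknown key or violation at once. An empty
#' or missing-section file yields the full default bundle.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config, or `NULL` for pure
#'   defaults.
#' @return Named list with `network` ([network_config()]), `train`
#'   ([train_config()]), and `measure` settings.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config_bundle()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  problems <- character()
  unknown_top <- setdiff(names(user), names(defaults))
  if (length(unknown_top)) {
    problems <- c(problems, sprintf("unknown section(s): %s",
                                    paste(unknown_top, collapse = ", ")))
  }
  merged <- defaults
  for (sec in intersect(names(user), names(defaults))) {
    unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(unknown)) {
      problems <- c(problems, sprintf("unknown key(s) in %s: %s", sec,
                                      paste(unknown, collapse = ", ")))
    }
    for (key in intersect(names(user[[sec]]), names(defaults[[sec]]))) {
      merged[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  if (length(problems)) abort(paste(problems, collapse = "; "))
  ctor_args <- function(ctor, values) {
    values[intersect(names(values), names(formals(ctor)))]
  }
  bundle <- list(
    network = tryCatch(do.call(network_config, ctor_args(network_config, merged$network)),
                       error = function(e) e),
    train = tryCatch(do.call(train_config, ctor_args(train_config, merged$train)),
                     error = function(e) e),
    measure = merged$measure)
  errs <- purrr::keep(bundle, inherits, "error")
  if (length(errs)) {
    abort(paste(vapply(errs, conditionMessage, character(1)), collapse = "; "))
  }
  bundle
}

#' Save a configuration bundle to YAML or JSON
#'
#' @param bundle A bundle as returned by [load_config()].
#' @param path Target path; format chosen by extension.
#' @return The path, invisibly.
#' @export
save_config <- function(bundle, path) {
  plain <- list(network = unclass(bundle$network),
                train = unclass(bundle$train),
                measure = bundle$measure)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA), path)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}
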