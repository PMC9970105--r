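# Landscape-scale classification ----------------------------------------
#
# A severity landscape is a gridded RdNBR surface plus a per-pixel potential
# vegetation type (dry mixed conifer, ponderosa pine, or other). Forest
# pixels are reclassified into restoration-probability classes from the
# restorative severity ranges of the matching vegetation type; "other"
# pixels are masked.

RESTORATION_CLASSES <- c(
  "too_cold_lt50", "cold_50_to_75", "restorative_ge75",
  "hot_50_to_75", "too_hot_lt50"
)

#' Construct a severity landscape
#'
#' @param severity Numeric matrix of per-pixel RdNBR values.
#' @param veg_type Character matrix (same dimensions) of vegetation types:
#'   `"dry_mixed_conifer"`, `"ponderosa_pine"`, or `"other"` (maskable).
#' @param pixel_size Pixel edge length in metres (default 30).
#' @return An object of class `severity_landscape`.
#' @export
severity_landscape <- function(severity, veg_type, pixel_size = 30) {
  if (!is.matrix(severity) || !is.matrix(veg_type)) {
    abort("`severity` and `veg_type` must be matrices.")
  }
  if (!identical(dim(severity), dim(veg_type))) {
    abort("`severity` and `veg_type` must have identical dimensions.")
  }
  if (any(dim(severity) < 1)) abort("landscape dimensions must be positive.")
  bad <- !veg_type %in% c(FOREST_TYPES, "other")
  if (any(bad)) {
    abort(paste0(
      "unknown vegetation type(s): ",
      paste(unique(veg_type[bad]), collapse = ", ")
    ))
  }
  structure(
    list(severity = severity, veg_type = veg_type, pixel_size = pixel_size),
    class = "severity_landscape"
  )
}

#' @export
print.severity_landscape <- function(x, ...) {
  d <- dim(x$severity)
  cat("<severity_landscape> ", d[1], " x ", d[2], " pixels (",
    x$pixel_size, " m)\n",
    sep = ""
  )
  cat(
    "RdNBR range: ", round(min(x$severity), 1), "..",
    round(max(x$severity), 1), "\n",
    sep = ""
  )
  tab <- table(x$veg_type)
  cat("veg types: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy severity_landscape
#' @export
tidy.severity_landscape <- function(x, ...) {
  d <- dim(x$severity)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    severity = as.vector(x$severity),
    veg_type = as.vector(x$veg_type)
  )
}

#' Reclassify a severity landscape into restoration-probability classes
#'
#' Per unmasked forest pixel: severity inside the vegetation type's
#' >= 0.75 restorative range maps to `restorative_ge75`; otherwise inside the
#' >= 0.50 range maps to `cold_50_to_75` below the 0.75 range or
#' `hot_50_to_75` above it; otherwise `too_cold_lt50` below the 0.50 range or
#' `too_hot_lt50` above it. Range endpoints are inclusive. Pixels of the
#' `"other"` vegetation type are masked (`NA`).
#'
#' @param landscape A [severity_landscape()].
#' @param ranges Range tibble (as from [restorative_ranges()]) holding, for
#'   each forest vegetation type present, nonempty rows at thresholds 0.75
#'   and 0.50 for one metric.
#' @param metric Classification metric (default `"basal_area"`).
#' @return An object of class `restoration_class_map`: integer class-code
#'   matrix plus a `legend` tibble.
#' @export
classify_pixels <- function(landscape, ranges, metric = "basal_area") {
  ranges <- ranges[ranges$metric == metric, ]
  types_present <- intersect(unique(as.vector(landscape$veg_type)), FOREST_TYPES)
  lims <- list()
  for (ft in types_present) {
    r75 <- ranges[ranges$forest_type == ft & ranges$threshold == 0.75, ]
    r50 <- ranges[ranges$forest_type == ft & ranges$threshold == 0.50, ]
    if (nrow(r75) != 1 || nrow(r50) != 1 || r75$empty || r50$empty) {
      abort(paste0(
        "missing or empty restorative range (0.75 and 0.50 needed) for ",
        "vegetation type: ", ft
      ))
    }
    lims[[ft]] <- c(lo75 = r75$lo, hi75 = r75$hi, lo50 = r50$lo, hi50 = r50$hi)
  }
  sev <- landscape$severity
  veg <- landscape$veg_type
  cls <- matrix(NA_integer_, nrow(sev), ncol(sev))
  for (ft in types_present) {
    b <- lims[[ft]]
    ix <- veg == ft
    s <- sev[ix]
    v <- integer(length(s))
    v[s < b["lo50"]] <- 1L
    v[s >= b["lo50"] & s < b["lo75"]] <- 2L
    v[s >= b["lo75"] & s <= b["hi75"]] <- 3L
    v[s > b["hi75"] & s <= b["hi50"]] <- 4L
    v[s > b["hi50"]] <- 5L
    cls[ix] <- v
  }
  legend <- tibble::tibble(
    code = 1:5,
    class = RESTORATION_CLASSES,
    description = c(
      "restoration probability < 0.50, below the restorative range (too cold)",
      "restoration probability 0.50-0.75, below the 0.75 range",
      "restoration probability >= 0.75",
      "restoration probability 0.50-0.75, above the 0.75 range",
      "restoration probability < 0.50, above the restorative range (too hot)"
    )
  )
  structure(
    list(class = cls, legend = legend, metric = metric),
    class = "restoration_class_map"
  )
}

#' @export
print.restoration_class_map <- function(x, ...) {
  d <- dim(x$class)
  cat("<restoration_class_map> ", d[1], " x ", d[2], " pixels, metric: ",
    x$metric, "\n",
    sep = ""
  )
  tab <- table(factor(x$class, levels = 1:5, labels = RESTORATION_CLASSES),
    useNA = "always"
  )
  print(tab)
  invisible(x)
}

#' @method tidy restoration_class_map
#' @export
tidy.restoration_class_map <- function(x, ...) {
  d <- dim(x$class)
  code <- as.vector(x$class)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    code = code,
    class = ifelse(is.na(code), "masked", RESTORATION_CLASSES[code])
  )
}

#' Class-proportion summary of a restoration class map
#'
#' Proportions of pixels per restoration class, overall and by vegetation
#' type, over two bases: unmasked forest pixels (`prop`) and all pixels
#' (`prop_all`). Cumulative rows `ge75` (restorative class) and `ge50`
#' (restorative plus both 0.50-0.75 classes) are included, along with
#' `lt50_too_cold` / `lt50_too_hot` splits.
#'
#' @param map A `restoration_class_map` from [classify_pixels()].
#' @param landscape The congruent [severity_landscape()].
#' @return Tibble with columns `veg_type` (including `"all"`), `measure`,
#'   `n`, `prop`, `prop_all`.
#' @export
class_summary <- function(map, landscape) {
  if (!identical(dim(map$class), dim(landscape$severity))) {
    abort("class map and landscape are not congruent.")
  }
  code <- as.vector(map$class)
  veg <- as.vector(landscape$veg_type)
  n_all <- length(code)
  one_basis <- function(sel, label) {
    cd <- code[sel]
    n_forest <- sum(!is.na(cd))
    counts <- tabulate(cd[!is.na(cd)], nbins = 5)
    measures <- c(RESTORATION_CLASSES, "ge75", "ge50", "lt50_too_cold", "lt50_too_hot", "masked")
    n <- c(
      counts,
      counts[3],
      counts[2] + counts[3] + counts[4],
      counts[1],
      counts[5],
      sum(is.na(cd))
    )
    tibble::tibble(
      veg_type = label,
      measure = measures,
      n = n,
      prop = ifelse(measures == "masked", NA_real_, n / max(n_forest, 1)),
      prop_all = n / max(sum(sel), 1)
    )
  }
  out <- one_basis(rep(TRUE, n_all), "all")
  for (ft in intersect(unique(veg), FOREST_TYPES)) {
    out <- dplyr::bind_rows(out, one_basis(veg == ft, ft))
  }
  out
}

#' Residual stand structure by species and diameter class
#'
#' Simulates template stands at selected severities and tabulates the mean
#' live basal area per hectare by species group and DBH bin, averaged over
#' stands and iterations (the composition-by-size profile of the surviving
#' stand).
#'
#' @param models Named list of [mortality_model()] objects.
#' @param stands Standardized stand tibble (template stands, e.g. one
#'   forest x type).
#' @param severities RdNBR values at which to simulate.
#' @param iterations Iterations per stand x severity (default 30).
#' @param dbh_bins Bin edges in cm (default `c(15, 30, 45, 60, 75, Inf)`).
#' @param years Years post-fire (default 3).
#' @param seed Optional seed.
#' @return Tibble `severity`, `species_group`, `dbh_bin`, `ba_live_mean`
#'   (m^2/ha, mean over stands and iterations).
#' @export
residual_structure <- function(models, stands, severities, iterations = 30,
                               dbh_bins = c(15, 30, 45, 60, 75, Inf),
                               years = 3, seed = NULL) {
  if (length(dbh_bins) < 2) abort("`dbh_bins` needs at least two edges.")
  if (nrow(stands) == 0) abort("empty stand collection.")
  check_models_cover(stands, models)
  if (!is.null(seed)) set.seed(seed)
  n_stands <- length(unique(stands$stand_id))
  bin_labels <- paste0(
    "[", head(dbh_bins, -1), ",",
    ifelse(is.finite(tail(dbh_bins, -1)), tail(dbh_bins, -1), "Inf"), ")"
  )
  res <- list()
  for (sev in severities) {
    acc <- NULL
    for (id in unique(stands$stand_id)) {
      st <- stands[stands$stand_id == id, , drop = FALSE]
      n <- nrow(st)
      tree_ix <- rep.int(seq_len(n), iterations)
      iter <- rep(seq_len(iterations), each = n)
      live <- .sim_live(
        st$species_group[tree_ix], st$dbh[tree_ix],
        rep(sev, n * iterations), iter, models, years, FALSE
      )
      ba <- st$expf[tree_ix] * tree_basal_area(st$dbh[tree_ix])
      bin <- cut(st$dbh[tree_ix], dbh_bins, right = FALSE, labels = bin_labels)
      d <- tibble::tibble(
        species_group = st$species_group[tree_ix],
        dbh_bin = as.character(bin),
        ba_live = ba * live
      )
      acc <- dplyr::bind_rows(acc, d)
    }
    sums <- dplyr::summarise(
      dplyr::group_by(acc, .data$species_group, .data$dbh_bin),
      ba_live_mean = sum(.data$ba_live) / (n_stands * iterations),
      .groups = "drop"
    )
    sums$severity <- sev
    res[[length(res) + 1]] <- sums
  }
  out <- dplyr::bind_rows(res)
  out$dbh_bin <- factor(out$dbh_bin, levels = bin_labels)
  dplyr::select(
    out, "severity", "species_group", "dbh_bin", "ba_live_mean"
  )
}

# ASCII grid I/O ----------------------------------------------------------

#' Write a matrix as a headered ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, top row first.
#'
#' @param mat Numeric (or integer) matrix; `NA` written as the nodata value.
#' @param path Output file path.
#' @param cellsize Pixel size in metres.
#' @param nodata Nodata sentinel (default -9999).
#' @export
write_ascii_grid <- function(mat, path, cellsize = 30, nodata = -9999) {
  header <- c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", 0),
    paste("yllcorner", 0),
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  )
  m <- mat
  m[is.na(m)] <- nodata
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a headered ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any conforming
#'   ASCII grid).
#' @return Numeric matrix with `NA` for nodata; attributes `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[`, "", 1)
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  body <- lines[-(1:6)]
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  m <- do.call(rbind, rows)
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"]) {
    abort("ASCII grid body does not match its header dimensions.")
  }
  m[m == vals["nodata_value"]] <- NA
  attr(m, "cellsize") <- unname(vals["cellsize"])
  m
}

#' Write a severity landscape to ASCII grids
#'
#' Severity goes to `<stem>_rdnbr.asc`; vegetation type to `<stem>_pvt.asc`
#' coded 1 = dry mixed conifer, 2 = ponderosa pine, 0 = other.
#'
#' @param landscape A [severity_landscape()].
#' @param stem Path stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_landscape <- function(landscape, stem) {
  p1 <- paste0(stem, "_rdnbr.asc")
  p2 <- paste0(stem, "_pvt.asc")
  write_ascii_grid(landscape$severity, p1, cellsize = landscape$pixel_size)
  veg_code <- matrix(
    match(landscape$veg_type, FOREST_TYPES, nomatch = 0),
    nrow(landscape$veg_type)
  )
  write_ascii_grid(veg_code, p2, cellsize = landscape$pixel_size)
  invisible(c(p1, p2))
}

#' Read a severity landscape from ASCII grids
#'
#' @param stem Path stem used by [write_landscape()].
#' @return A [severity_landscape()].
#' @export
read_landscape <- function(stem) {
  sev <- read_ascii_grid(paste0(stem, "_rdnbr.asc"))
  veg_code <- read_ascii_grid(paste0(stem, "_pvt.asc"))
  cs <- attr(sev, "cellsize") %||% 30
  veg <- matrix(c("other", FOREST_TYPES)[veg_code + 1], nrow(veg_code))
  attr(sev, "cellsize") <- NULL
  severity_landscape(sev, veg, pixel_size = cs)
}
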