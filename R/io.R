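# Reading and writing the plain-text exchange formats: two/three-column
# numeric tables with "# key: value" metadata headers, manifest CSVs, and
# a minimal JCAMP-DX reader for infrared spectra.

read_meta_table <- function(file, n_cols) {
  lines <- readLines(file, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*[:=]\\s*(.+)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- suppressWarnings(as.numeric(m[3]))
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  con <- textConnection(body)
  on.exit(close(con))
  dat <- utils::read.table(con, header = FALSE, sep = "",
                           colClasses = "numeric",
                           col.names = paste0("V", seq_len(n_cols)))
  # comma-delimited fallback
  if (ncol(dat) < n_cols || anyNA(dat)) {
    con2 <- textConnection(body)
    dat <- utils::read.csv(con2, header = FALSE,
                           col.names = paste0("V", seq_len(n_cols)))
    close(con2)
  }
  list(data = dat, meta = meta)
}

meta_or_na <- function(meta, key, override) {
  if (!is.na(override)) return(override)
  if (!is.null(meta[[key]])) return(meta[[key]])
  NA_real_
}

#' Read and write SAXS patterns as two-column text
#'
#' The on-disk format is whitespace- or comma-delimited `q intensity`
#' pairs, with optional `# temperature_C: x` and `# water_wt: x` header
#' lines. A unit flag converts Angstrom^-1 input to the internal nm^-1.
#'
#' @param file path.
#' @param unit `"nm-1"` (default) or `"angstrom-1"` (values multiplied by
#'   10 on read).
#' @param temperature,water_wt override the header metadata.
#' @return [read_saxs_pattern()] returns a [saxs_pattern()];
#'   `write_saxs_pattern` returns `file` invisibly.
#' @export
read_saxs_pattern <- function(file, unit = c("nm-1", "angstrom-1"),
                              temperature = NA_real_, water_wt = NA_real_) {
  unit <- match.arg(unit)
  r <- read_meta_table(file, 2L)
  q <- r$data$V1
  if (unit == "angstrom-1") q <- q * 10
  saxs_pattern(q, r$data$V2,
               temperature = meta_or_na(r$meta, "temperature_C", temperature),
               water_wt = meta_or_na(r$meta, "water_wt", water_wt))
}

#' @rdname read_saxs_pattern
#' @param pattern a [saxs_pattern()].
#' @export
write_saxs_pattern <- function(pattern, file) {
  stopifnot(inherits(pattern, "saxs_pattern"))
  hdr <- c(sprintf("# temperature_C: %g", pattern$temperature),
           sprintf("# water_wt: %g", pattern$water_wt))
  writeLines(c(hdr, paste(format(pattern$q, digits = 10),
                          format(pattern$intensity, digits = 10))), file)
  invisible(file)
}

#' Read and write dielectric spectra as three-column text
#'
#' Columns are `frequency_Hz eps_real eps_imag`, with the same metadata
#' header convention as [read_saxs_pattern()].
#'
#' @param file path.
#' @param temperature,water_wt override the header metadata.
#' @return A `"dielectric_spectrum"`; the writer returns `file` invisibly.
#' @export
read_dielectric_spectrum <- function(file, temperature = NA_real_,
                                     water_wt = NA_real_) {
  r <- read_meta_table(file, 3L)
  dielectric_spectrum(r$data$V1, r$data$V2, r$data$V3,
                      temperature = meta_or_na(r$meta, "temperature_C", temperature),
                      water_wt = meta_or_na(r$meta, "water_wt", water_wt))
}

#' @rdname read_dielectric_spectrum
#' @param spectrum a `"dielectric_spectrum"`.
#' @export
write_dielectric_spectrum <- function(spectrum, file) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  hdr <- c(sprintf("# temperature_C: %g", spectrum$temperature),
           sprintf("# water_wt: %g", spectrum$water_wt))
  writeLines(c(hdr, paste(format(spectrum$frequency, digits = 10),
                          format(spectrum$eps_real, digits = 10),
                          format(spectrum$eps_imag, digits = 10))), file)
  invisible(file)
}

#' Read and write FTIR spectra (two-column text or JCAMP-DX)
#'
#' Plain tables follow the `wavenumber_cm-1 absorbance` convention with
#' metadata headers. Files whose first non-blank line starts with `##` are
#' parsed as JCAMP-DX; the reader understands AFFN-encoded
#' `##XYDATA=(X++(Y..Y))` blocks and `##XYPOINTS=(XY..XY)` tables (no
#' compressed SQZ/DIF forms), honouring XFACTOR/YFACTOR scaling.
#'
#' @param file path.
#' @param format `"auto"` (default), `"table"`, or `"jcamp"`.
#' @param temperature,water_wt override metadata.
#' @return An [ftir_spectrum()]; the writer returns `file` invisibly.
#' @export
read_ftir_spectrum <- function(file, format = c("auto", "table", "jcamp"),
                               temperature = NA_real_, water_wt = NA_real_) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(file, n = 5L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && startsWith(trimws(first[1]), "##"))
      "jcamp" else "table"
  }
  if (format == "jcamp") return(read_jcamp(file, temperature, water_wt))
  r <- read_meta_table(file, 2L)
  o <- order(r$data$V1)
  ftir_spectrum(r$data$V1[o], r$data$V2[o],
                temperature = meta_or_na(r$meta, "temperature_C", temperature),
                water_wt = meta_or_na(r$meta, "water_wt", water_wt))
}

#' @rdname read_ftir_spectrum
#' @param spectrum an [ftir_spectrum()].
#' @export
write_ftir_spectrum <- function(spectrum, file) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  hdr <- c(sprintf("# temperature_C: %g", spectrum$temperature),
           sprintf("# water_wt: %g", spectrum$water_wt))
  writeLines(c(hdr, paste(format(spectrum$wavenumber, digits = 10),
                          format(spectrum$absorbance, digits = 10))), file)
  invisible(file)
}

# Minimal JCAMP-DX parser: AFFN numeric forms only.
read_jcamp <- function(file, temperature = NA_real_, water_wt = NA_real_) {
  lines <- readLines(file, warn = FALSE)
  get_field <- function(key) {
    i <- grep(paste0("^##", key, "\\s*="), lines, ignore.case = TRUE)
    if (!length(i)) return(NA_character_)
    trimws(sub("^##[^=]*=", "", lines[i[1]]))
  }
  xfac <- suppressWarnings(as.numeric(get_field("XFACTOR"))); if (is.na(xfac)) xfac <- 1
  yfac <- suppressWarnings(as.numeric(get_field("YFACTOR"))); if (is.na(yfac)) yfac <- 1
  tC <- suppressWarnings(as.numeric(get_field("TEMPERATURE")))

  start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  xs <- numeric(0); ys <- numeric(0)
  if (length(start)) {
    i <- start[1] + 1L
    while (i <= length(lines) && !startsWith(trimws(lines[i]), "##")) {
      nums <- as.numeric(strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]])
      nums <- nums[!is.na(nums)]
      if (length(nums) >= 2L) {
        x0 <- nums[1]; yy <- nums[-1]
        # x increment from declared grid when available, else from the next line
        xs <- c(xs, rep(x0, length(yy)))  # placeholder, fixed below
        ys <- c(ys, yy)
      }
      i <- i + 1L
    }
    # rebuild x: lines give the x of their first y; interpolate within lines
    firstx <- suppressWarnings(as.numeric(get_field("FIRSTX")))
    lastx <- suppressWarnings(as.numeric(get_field("LASTX")))
    npts <- suppressWarnings(as.numeric(get_field("NPOINTS")))
    if (!is.na(firstx) && !is.na(lastx) && !is.na(npts) && npts >= 2) {
      xs <- seq(firstx, lastx, length.out = npts) * xfac
      ys <- ys[seq_len(min(length(ys), npts))]
      xs <- xs[seq_along(ys)]
    } else {
      stop_mesokit("JCAMP XYDATA without FIRSTX/LASTX/NPOINTS is not supported",
                   "mesokit_validation")
    }
  } else {
    start <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
    if (!length(start))
      stop_mesokit("no XYDATA or XYPOINTS block found", "mesokit_validation")
    i <- start[1] + 1L
    while (i <= length(lines) && !startsWith(trimws(lines[i]), "##")) {
      nums <- as.numeric(strsplit(trimws(lines[i]), "[,;[:space:]]+")[[1]])
      nums <- nums[!is.na(nums)]
      if (length(nums) >= 2L) {
        xs <- c(xs, nums[seq(1, length(nums) - 1, by = 2)] * xfac)
        ys <- c(ys, nums[seq(2, length(nums), by = 2)])
      }
      i <- i + 1L
    }
  }
  ys <- ys * yfac
  o <- order(xs)
  ftir_spectrum(xs[o], ys[o],
                temperature = if (!is.na(temperature)) temperature else tC,
                water_wt = water_wt)
}

#' Read a series manifest
#'
#' A manifest is a CSV with columns `file`, `temperature`, `water_wt`
#' (paths relative to the manifest's directory).
#'
#' @param file manifest path.
#' @return Data frame with absolute `file` paths.
#' @export
read_manifest <- function(file) {
  m <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("file", "temperature", "water_wt")
  if (!all(need %in% names(m)))
    stop_mesokit("manifest needs columns file, temperature, water_wt",
                 "mesokit_validation")
  if (!nrow(m))
    stop_mesokit("manifest is empty", "mesokit_validation")
  m$file <- file.path(dirname(normalizePath(file)), m$file)
  missing <- !file.exists(m$file)
  if (any(missing))
    stop_mesokit(paste("manifest references missing file(s):",
                       paste(basename(m$file[missing]), collapse = ", ")),
                 "mesokit_validation")
  m
}

#' Load a full series from a manifest
#'
#' @param file manifest path.
#' @param modality `"saxs"`, `"bds"` or `"ftir"`.
#' @return A list of pattern/spectrum objects with manifest metadata
#'   attached.
#' @export
read_series <- function(file, modality = c("saxs", "bds", "ftir")) {
  modality <- match.arg(modality)
  m <- read_manifest(file)
  reader <- switch(modality, saxs = read_saxs_pattern,
                   bds = read_dielectric_spectrum, ftir = read_ftir_spectrum)
  lapply(seq_len(nrow(m)), function(i)
    reader(m$file[i], temperature = m$temperature[i],
           water_wt = m$water_wt[i]))
}

#' Write a scenario's synthetic file tree
#'
#' Generates the three modality series for a scenario and writes them under
#' `dir` as `saxs/`, `bds/`, `ftir/` subdirectories, each with numbered
#' data files and a `manifest.csv`, ready for [read_series()] and
#' [run_study()].
#'
#' @param scenario a [mesophase_scenario()].
#' @param dir output directory (created if needed).
#' @param seed RNG seed (defaults to the scenario's).
#' @return Named character vector of the three manifest paths, invisibly.
#' @export
write_scenario_tree <- function(scenario, dir, seed = scenario$seed) {
  stopifnot(inherits(scenario, "mesophase_scenario"))
  series <- list(saxs = gen_saxs_series(scenario, seed = seed),
                 bds = gen_bds_series(scenario, seed = seed + 1L),
                 ftir = gen_ftir_series(scenario, seed = seed + 2L))
  writers <- list(saxs = write_saxs_pattern, bds = write_dielectric_spectrum,
                  ftir = write_ftir_spectrum)
  exts <- list(saxs = "dat", bds = "csv", ftir = "dat")
  manifests <- character(0)
  for (mod in names(series)) {
    sub <- file.path(dir, mod)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(seq_along(series[[mod]]), function(i) {
      obj <- series[[mod]][[i]]
      fn <- sprintf("%s_%03d.%s", mod, i, exts[[mod]])
      writers[[mod]](obj, file.path(sub, fn))
      data.frame(file = fn, temperature = obj$temperature,
                 water_wt = obj$water_wt)
    })
    mf <- file.path(sub, "manifest.csv")
    utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
    manifests[mod] <- mf
  }
  invisible(manifests)
}
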