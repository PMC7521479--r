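#' Write a kymograph to delimited text
#'
#' Dialect: tab-separated; first row holds the frame times (min) with an
#' empty top-left cell, first column the spatial coordinate (um), body cells
#' the intensity. Floats are written with 9 significant digits. Domain
#' topology, normalization state, and any DNA track are written to a sidecar
#' `<path>.meta.yml` so the object round-trips.
#'
#' @param kymo A [kymograph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  fmt <- function(v) formatC(v, digits = 9, format = "g")
  header <- paste(c("", fmt(kymo$t)), collapse = "\t")
  rows <- vapply(seq_along(kymo$x), function(i) {
    paste(c(fmt(kymo$x[i]), fmt(kymo$I[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  meta <- list(L = kymo$L, periodic = kymo$periodic,
               normalization = kymo$normalization)
  if (!is.null(kymo$dna)) {
    meta$dna_t <- kymo$dna$t
    meta$dna_xn <- kymo$dna$xn
    if ("w" %in% names(kymo$dna)) meta$dna_w <- kymo$dna$w
  }
  write_flat_keyvals(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

# Flat "key: value" text serialization with exact double round-trip
# (%.17g); vectors are comma-joined, logicals lowercase true/false.
write_flat_keyvals <- function(params, path) {
  fmt1 <- function(v) {
    if (is.logical(v)) return(ifelse(v, "true", "false"))
    if (is.numeric(v)) return(formatC(v, digits = 17, format = "g"))
    as.character(v)
  }
  lines <- vapply(names(params), function(k) {
    paste0(k, ": ", paste(fmt1(params[[k]]), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_flat_keyvals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (l in lines) {
    i <- regexpr(": ", l, fixed = TRUE)
    if (i < 0) next
    key <- substr(l, 1, i - 1)
    val <- strsplit(substring(l, i + 2), ", ", fixed = TRUE)[[1]]
    if (all(val %in% c("true", "false"))) {
      val <- val == "true"
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!anyNA(num)) val <- num
    }
    out[[key]] <- val
  }
  out
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path File path.
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  t <- as.numeric(header[-1])
  body <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  x <- body[, 1]
  I <- body[, -1, drop = FALSE]
  meta_path <- paste0(path, ".meta.yml")
  dna <- NULL
  L <- max(x) + (x[2] - x[1])
  periodic <- TRUE
  normalization <- "raw"
  if (file.exists(meta_path)) {
    meta <- read_flat_keyvals(meta_path)
    L <- meta$L
    periodic <- meta$periodic
    normalization <- meta$normalization
    if (!is.null(meta$dna_t)) {
      dna <- data.frame(t = meta$dna_t, xn = meta$dna_xn)
      if (!is.null(meta$dna_w)) dna$w <- meta$dna_w
    }
  }
  kymograph(x, t, I, dna = dna, L = L, periodic = periodic,
            normalization = normalization)
}

#' Write a position track
#'
#' Columns `t_min`, `xn_um` (and `y_um` for 2D tracks), tab-separated, 9
#' significant digits.
#'
#' @param track A [trajectory()] or data frame with `t` and `x` (and `y`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  fmt <- function(v) formatC(v, digits = 9, format = "g")
  cols <- c("t_min", "xn_um", if ("y" %in% names(track)) "y_um")
  vals <- cbind(fmt(track$t), fmt(track$x),
                if ("y" %in% names(track)) fmt(track$y))
  writeLines(c(paste(cols, collapse = "\t"),
               apply(vals, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a track written by [write_track()]
#'
#' @param path File path.
#' @return A [trajectory()].
#' @export
read_track <- function(path) {
  df <- utils::read.delim(path)
  if ("y_um" %in% names(df)) {
    trajectory(df$t_min, cbind(df$xn_um, df$y_um))
  } else {
    trajectory(df$t_min, df$xn_um)
  }
}

#' Write a run manifest
#'
#' Flat key-value structured text (one `key: value` line per parameter)
#' recording every parameter, seed, and the package version. Floats are
#' written with 17 significant digits so that doubles round-trip exactly
#' and any result file can be regenerated bit-identically from its
#' manifest.
#'
#' @param params Named list (scalars or numeric vectors).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  stopifnot(is.list(params), !is.null(names(params)))
  params$package_version <- as.character(utils::packageVersion("spindlecortex"))
  write_flat_keyvals(params, path)
}

#' Read a run manifest
#'
#' @param path File path.
#' @return Named list.
#' @export
read_manifest <- function(path) read_flat_keyvals(path)

run_config_defaults <- function() {
  list(
    # cortical kinetics
    D = 0.01, koff_near = 0.1, koff_far = 1 / 90, b = 1 / 90, sigma = 0.5,
    # geometry
    L = 80, dx = 0.2, periodic = TRUE, w_dna = 4, d_inh = 4,
    # spindle / microtubules
    v0 = 6.7, delta = 0, mt_mean = 6, mt_max = 20,
    # integration
    T = 450, dt = 0.05, save_dt = 1, seed = 1L, perturb_amp = 1e-3,
    # 2D rounding / orientation
    a0 = 20, b0 = 7, R = 10, tau_round = 4, t_bipolar = 9,
    half_sep = 5, w_plate = 6, r_dna = 5, mu_r = 0.5,
    lgn_scale = 1, n_nodes = 256L,
    # synthetic data
    frame_interval = 3, noise_mult_sd = 0.1, noise_bg_mean = 0.05,
    noise_bg_sd = 0.02
  )
}

#' Run configuration
#'
#' All model and quantification parameters with their defaults; unknown keys
#' are rejected. A configuration round-trips through a manifest file
#' unchanged.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("run_config overrides must be named")
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  structure(cfg, class = "run_config")
}

#' Model components from a configuration
#'
#' @param cfg A [run_config()].
#' @return A list with `kinetics`, `domain`, `mt`, `spindle` (monopolar,
#'   centred), `noise`.
#' @export
config_models <- function(cfg) {
  dom <- domain_1d(cfg$L, cfg$dx, cfg$periodic)
  list(
    kinetics = lgn_kinetics(D = cfg$D, koff_near = cfg$koff_near,
                            koff_far = cfg$koff_far, b = cfg$b,
                            sigma = cfg$sigma),
    domain = dom,
    mt = mt_exponential(cfg$mt_mean, cfg$mt_max),
    spindle = monopolar_spindle(dom$L / 2, cfg$delta, cfg$v0),
    noise = noise_model(cfg$noise_mult_sd, cfg$noise_bg_mean, cfg$noise_bg_sd)
  )
}
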