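## Flat key-value run configuration ("key = value" per line, '#' comments).
## Unknown keys are rejected so typos cannot silently fall back to
## defaults; every run logs the resolved configuration.

.configKeys <- local({
  simKeys <- c("spacegroup", "cell", "dmin", "n_patterns", "wavelength",
               "distance", "distance_true", "pixel", "center", "extent",
               "n_atoms", "n_sulfur", "b_iso", "f_prime", "f_double_prime",
               "model_seed", "cell_jitter", "scale_sd_log", "b_jitter",
               "profile_radius", "profile_jitter_log", "sigma_bg",
               "spot_sigma", "photon_scale", "noise", "partiality_mode",
               "min_peaks")
  c("seed", paste0("sim.", simKeys),
    "merge.model", "merge.iterations", "merge.push_res",
    "merge.outlier_nsigma", "merge.min_measurements", "merge.min_partiality",
    "metrics.shells", "study.sizes", "study.threshold")
})

.parseConfigValue <- function(v) {
  v <- trimws(v)
  parts <- strsplit(v, "[, ]+")[[1]]
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  if (length(parts) == 1 && toupper(parts) %in% c("TRUE", "FALSE"))
    return(as.logical(toupper(parts)))
  v
}

#' Read a run configuration file
#'
#' Flat `key = value` lines; `#` starts a comment.  Keys use dotted
#' prefixes (`sim.`, `merge.`, `metrics.`, `study.`) plus a bare `seed`.
#' Unknown keys are an error.
#'
#' @param path configuration file
#' @return nested list: seed, sim ([simConfig()]), merge ([mergeConfig()]),
#'   metrics (list), study (list)
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+) *= *(.*)$", ln))[[1]]
    if (length(m) != 3) stop("bad config line: '", ln, "'")
    if (!(m[2] %in% .configKeys)) stop("unknown config key: ", m[2])
    kv[[m[2]]] <- .parseConfigValue(m[3])
  }
  pick <- function(prefix) {
    keys <- grep(paste0("^", prefix, "\\."), names(kv), value = TRUE)
    setNames(kv[keys], sub(paste0("^", prefix, "\\."), "", keys))
  }
  simRaw <- pick("sim")
  names(simRaw) <- vapply(names(simRaw), function(n)
    gsub("_(.)", "\\U\\1", n, perl = TRUE), "")
  sim <- do.call(simConfig, simRaw)
  mr <- pick("merge")
  merge <- mergeConfig(
    model = if (is.null(mr$model)) "xsphere" else mr$model,
    iterations = if (is.null(mr$iterations)) 1 else mr$iterations,
    pushRes = if (is.null(mr$push_res)) 0.5 else mr$push_res,
    outlierNsigma = if (is.null(mr$outlier_nsigma)) 4 else mr$outlier_nsigma,
    minMeasurements = if (is.null(mr$min_measurements)) 2
                      else mr$min_measurements,
    minPartiality = if (is.null(mr$min_partiality)) 0.05
                    else mr$min_partiality)
  mt <- pick("metrics")
  st <- pick("study")
  list(seed = if (is.null(kv$seed)) 1 else kv$seed,
       sim = sim, merge = merge,
       metrics = list(shells = if (is.null(mt$shells)) 10 else mt$shells),
       study = list(sizes = st$sizes,
                    threshold = if (is.null(st$threshold)) 10
                                else st$threshold))
}
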