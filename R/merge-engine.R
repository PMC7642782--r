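## Monte Carlo merging of partial intensities.
##
## Pipeline (runMerge): initial unscaled Monte Carlo merge as reference ->
## (iterations x) [per-crystal scaling -> (xsphere only) partiality
## post-refinement -> re-merge] -> per-crystal resolution push -> robust
## outlier rejection -> final merge.  The "unity" model sets all
## partialities to 1 (plain Monte Carlo averaging); "xsphere" divides each
## observation by its spherical-cap partiality before averaging.

#' Merge configuration
#'
#' @param model "xsphere" (partiality-corrected) or "unity"
#' @param iterations scaling/post-refinement cycles (default 1)
#' @param pushRes per-crystal resolution push beyond the I/sigma >= 1
#'   diffraction limit, in 1/nm (`Inf` disables the filter)
#' @param outlierNsigma median/MAD rejection threshold (`Inf` disables)
#' @param minMeasurements minimum measurements per merged reflection
#' @param minPartiality xsphere observations with estimated partiality
#'   below this are excluded from corrected averages (guards against
#'   amplifying noise by 1/p)
#' @return a list of class `MergeConfig`
#' @export
mergeConfig <- function(model = c("xsphere", "unity"), iterations = 1,
                        pushRes = 0.5, outlierNsigma = 4,
                        minMeasurements = 2, minPartiality = 0.05) {
  model <- match.arg(model)
  stopifnot(iterations >= 0, pushRes >= 0, outlierNsigma > 0,
            minMeasurements >= 1, minPartiality >= 0)
  structure(list(model = model, iterations = iterations, pushRes = pushRes,
                 outlierNsigma = outlierNsigma,
                 minMeasurements = minMeasurements,
                 minPartiality = minPartiality),
            class = c("MergeConfig", "list"))
}

## observation table with ASU assignment; the working currency of the
## merge engine
.mergePrep <- function(dataset) {
  obs <- dataset@observations
  if (!nrow(obs)) return(data.table())
  m <- mapToAsu(dataset@spacegroup, as.matrix(obs[, c("h", "k", "l")]))
  side <- ifelse(m$centric, 1L, m$friedel)   # centric: single side
  dt <- as.data.table(obs)
  dt[, `:=`(ah = m$asu[, 1], ak = m$asu[, 2], al = m$asu[, 3],
            side = side,
            keyS = .hklKey(m$asu) * 2 + (side > 0),
            stol2 = 1 / (4 * d^2), q = 1 / d,
            crystal = pattern_id)]
  dt
}

.stateInit <- function(dataset) {
  cr <- dataset@crystals
  data.frame(id = cr$id, s = 1, b = 0, R = cr$profileRadius,
             flagScale = FALSE, flagR = FALSE)
}

## corrected (inferred-full) intensities under a state
.corrected <- function(dt, state, config) {
  i <- match(dt$crystal, state$id)
  s <- state$s[i]; b <- state$b[i]
  if (config$model == "xsphere") {
    p <- partialityCap(dt$r, state$R[i])
    keepP <- p >= config$minPartiality
  } else {
    p <- rep(1, nrow(dt))
    keepP <- rep(TRUE, nrow(dt))
  }
  corr <- s * exp(-2 * b * dt$stol2) * p
  out <- dt[keepP]
  out[, `:=`(If = dt$intensity[keepP] / corr[keepP],
             sc = dt$sigma[keepP] / corr[keepP])]
  out
}

.mcMergeCorrected <- function(cdt, minMeasurements = 1L) {
  g <- cdt[, .(ah = ah[1], ak = ak[1], al = al[1], side = side[1],
               d = d[1], n = .N, Im = mean(If),
               Isd = if (.N >= 2) sd(If) else NA_real_,
               Iprop = sqrt(mean(sc^2))), by = keyS]
  g[, sigma := ifelse(n >= 2, pmax(Isd, Iprop) / sqrt(n), Iprop)]
  g[n >= minMeasurements]
}

.asMerged <- function(g, dataset, provenance) {
  rf <- data.frame(h = g$ah, k = g$ak, l = g$al, side = g$side,
                   intensity = g$Im, sigma = g$sigma, nmeas = g$n, d = g$d)
  rf <- rf[order(-rf$d, rf$h, rf$k, rf$l, -rf$side), ]
  rownames(rf) <- NULL
  new("MergedDataset", cell = dataset@cell, spacegroup = dataset@spacegroup,
      reflections = rf, provenance = provenance)
}

## per-crystal linear scaling against a reference merge:
## log(I_obs / (p I_ref)) = log s - 2 B stol^2
.scaleState <- function(dt, refG, state, config) {
  i <- match(dt$crystal, state$id)
  p <- if (config$model == "xsphere") partialityCap(dt$r, state$R[i])
       else rep(1, nrow(dt))
  Iref <- refG$Im[match(dt$keyS, refG$keyS)]
  valid <- is.finite(Iref) & Iref > 0 & dt$intensity > 0 &
    p >= max(config$minPartiality, 1e-6)
  w <- dt[valid]
  w[, `:=`(yv = log(intensity / (p[valid] * Iref[valid])), xv = stol2)]
  st <- w[, .(n = .N, mx = mean(xv), my = mean(yv),
              sxx = sum((xv - mean(xv))^2),
              sxy = sum((xv - mean(xv)) * (yv - mean(yv)))), by = crystal]
  st[, ok := n >= 3 & sxx > 0]
  st[, slope := ifelse(ok, sxy / sxx, 0)]
  st[, inter := ifelse(ok, my - slope * mx, 0)]
  newState <- state
  j <- match(newState$id, st$crystal)
  okv <- !is.na(j) & st$ok[ifelse(is.na(j), 1L, j)]
  inter <- ifelse(okv, st$inter[j], 0)
  slope <- ifelse(okv, st$slope[j], 0)
  if (any(okv)) inter <- inter - mean(inter[okv])  # normalize: mean log 0
  newState$s <- ifelse(okv, exp(inter), 1)
  newState$b <- ifelse(okv, -slope / 2, 0)
  newState$flagScale <- !okv
  newState
}

## one-dimensional per-crystal profile-radius refinement (xsphere)
.postrefineState <- function(dt, refG, state, config, bracket = c(0.25, 4)) {
  Iref <- refG$Im[match(dt$keyS, refG$keyS)]
  ok <- is.finite(Iref) & Iref > 0
  w <- dt[ok]
  IrefW <- Iref[ok]
  newState <- state
  grp <- split(seq_len(nrow(w)), w$crystal)
  for (cid in names(grp)) {
    ii <- grp[[cid]]
    si <- match(as.numeric(cid), state$id)
    s <- state$s[si]; b <- state$b[si]; R0 <- state$R[si]
    iobs <- w$intensity[ii]; rr <- w$r[ii]; st2 <- w$stol2[ii]
    irf <- IrefW[ii]
    pred <- s * exp(-2 * b * st2) * irf
    fres <- function(R) sum((iobs - pred * partialityCap(rr, R))^2)
    opt <- tryCatch(optimize(fres, interval = R0 * bracket),
                    error = function(e) NULL)
    if (is.null(opt)) { newState$flagR[si] <- TRUE; next }
    if (opt$objective <= fres(R0)) newState$R[si] <- opt$minimum
    else newState$flagR[si] <- TRUE
  }
  newState
}

## per-crystal diffraction limit (largest |q| with I/sigma >= 1) + push
.pushResLimits <- function(dt) {
  lim <- dt[intensity / sigma >= 1, .(limit = max(q)), by = crystal]
  setNames(lim$limit, lim$crystal)
}

.applyPushResDT <- function(dt, pushRes) {
  if (is.infinite(pushRes)) return(dt)
  lims <- .pushResLimits(dt)
  lim <- lims[as.character(dt$crystal)]
  lim[is.na(lim)] <- 0                      # crystal with no I/sigma>=1 obs
  dt[dt$q <= lim + pushRes / 10]            # pushRes nm^-1 -> A^-1
}

## median/MAD rejection within each merged reflection, two passes
.rejectOutliersDT <- function(cdt, nsigma, passes = 2L) {
  if (is.infinite(nsigma)) return(cdt)
  for (i in seq_len(passes)) {
    cdt[, keep := {
      med <- median(If)
      madv <- 1.4826 * median(abs(If - med))
      abs(If - med) <= nsigma * madv
    }, by = keyS]
    cdt <- cdt[keep == TRUE][, keep := NULL]
  }
  cdt
}

#' Robust outlier rejection for repeated measurements
#'
#' Median/MAD filter applied to the measurements of one merged reflection:
#' values with |I - median| > nsigma * 1.4826 * MAD are rejected; the rule
#' is applied for `passes` passes.
#'
#' @param x numeric vector of measurements of one reflection
#' @param nsigma rejection threshold (default 4)
#' @param passes number of passes (default 2)
#' @return logical vector: TRUE for retained measurements
#' @examples
#' rejectOutliers(c(10, 11, 9, 10, 50))   # the 50 goes
#' @export
rejectOutliers <- function(x, nsigma = 4, passes = 2L) {
  stopifnot(nsigma > 0)
  keep <- rep(TRUE, length(x))
  for (i in seq_len(passes)) {
    v <- x[keep]
    med <- median(v)
    madv <- 1.4826 * median(abs(v - med))
    keep[keep] <- abs(v - med) <= nsigma * madv
  }
  keep
}

#' Per-crystal scaling against a reference merge
#'
#' For each crystal, linear regression of log(I_obs / (p I_ref)) on
#' stol^2 over common reflections with positive quantities; the intercept
#' is the log scale and the slope is -2B.  Crystals with fewer than 3
#' usable reflections keep scale 1, B = 0 and are flagged.  Log scales are
#' centered so their mean is zero.
#'
#' @param dataset a [StillDataset-class]
#' @param reference optional [MergedDataset-class] used as I_ref; defaults
#'   to the unscaled Monte Carlo merge of `dataset`
#' @param config a [mergeConfig()]
#' @return data.frame: id, logScale, bFactor, flagged
#' @export
scaleCrystals <- function(dataset, reference = NULL,
                          config = mergeConfig()) {
  dt <- .mergePrep(dataset)
  state <- .stateInit(dataset)
  refG <- if (is.null(reference)) {
    .mcMergeCorrected(.corrected(dt, state, config), 1L)
  } else .refAsG(reference)
  st <- .scaleState(dt, refG, state, config)
  data.frame(id = st$id, logScale = log(st$s), bFactor = st$b,
             flagged = st$flagScale)
}

## MergedDataset -> internal group table keyed like .mcMergeCorrected output
.refAsG <- function(merged) {
  rf <- merged@reflections
  data.table(keyS = .hklKey(as.matrix(rf[, c("h", "k", "l")])) * 2 +
               (rf$side > 0),
             Im = rf$intensity)
}

#' Refine per-crystal profile radii (post-refinement)
#'
#' One-dimensional least-squares refinement of each crystal's profile
#' radius R against a reference merge, minimizing
#' sum (I_obs - s exp(-2B stol^2) p(r/R) I_ref)^2 over a bounded bracket
#' around the current value.  Crystals whose refinement fails (or does not
#' improve the residual) keep their prior R and are flagged.
#'
#' @param dataset a [StillDataset-class]
#' @param scales data.frame as returned by [scaleCrystals()] (NULL for
#'   scale 1, B 0)
#' @param reference a [MergedDataset-class] of reference intensities
#' @param config a [mergeConfig()] (model must be "xsphere")
#' @param bracket multiplicative search bracket around the current radius
#' @return data.frame: id, profileRadius, flagged
#' @export
postrefinePartiality <- function(dataset, scales = NULL, reference = NULL,
                                 config = mergeConfig(),
                                 bracket = c(0.25, 4)) {
  if (config$model != "xsphere")
    stop("partiality post-refinement requires model = 'xsphere'")
  dt <- .mergePrep(dataset)
  state <- .stateInit(dataset)
  if (!is.null(scales)) {
    i <- match(state$id, scales$id)
    state$s <- exp(scales$logScale[i])
    state$b <- scales$bFactor[i]
  }
  refG <- if (is.null(reference)) {
    .mcMergeCorrected(.corrected(dt, state, config), 1L)
  } else .refAsG(reference)
  st <- .postrefineState(dt, refG, state, config, bracket)
  data.frame(id = st$id, profileRadius = st$R, flagged = st$flagR)
}

#' Apply per-crystal resolution push
#'
#' Each crystal's diffraction limit is the largest |q| among its
#' observations with I/sigma >= 1; observations beyond limit + pushRes
#' (pushRes given in 1/nm, converted internally to 1/Angstrom) are
#' dropped.
#'
#' @param dataset a [StillDataset-class]
#' @param pushRes resolution push in 1/nm (`Inf` keeps everything)
#' @return the dataset with filtered observations
#' @export
applyPushRes <- function(dataset, pushRes = 0.5) {
  stopifnot(pushRes >= 0)
  if (is.infinite(pushRes)) return(dataset)
  obs <- dataset@observations
  dt <- data.table(crystal = obs$pattern_id, q = 1 / obs$d,
                   intensity = obs$intensity, sigma = obs$sigma)
  lims <- .pushResLimits(dt)
  lim <- lims[as.character(obs$pattern_id)]
  lim[is.na(lim)] <- 0
  initialize(dataset,
             observations = obs[1 / obs$d <= lim + pushRes / 10, ,
                                drop = FALSE])
}

#' Monte Carlo merge of corrected observations
#'
#' Each observation is corrected to an inferred full intensity
#' I_full = I_obs / (s exp(-2B stol^2) p) (p = 1 under the unity model),
#' mapped to its (ASU, Friedel side) record and averaged unweighted.
#' Sigma is the sample standard deviation over sqrt(n) for n >= 2, floored
#' by the propagated estimate, and the propagated single-measurement error
#' for n = 1.
#'
#' @param dataset a [StillDataset-class]
#' @param scales data.frame from [scaleCrystals()] (NULL: scale 1, B 0)
#' @param radii data.frame from [postrefinePartiality()] (NULL: stored
#'   per-crystal radii)
#' @param config a [mergeConfig()]
#' @return a [MergedDataset-class]
#' @export
mergeMonteCarlo <- function(dataset, scales = NULL, radii = NULL,
                            config = mergeConfig()) {
  dt <- .mergePrep(dataset)
  if (!nrow(dt))
    return(.asMerged(data.table(keyS = numeric(), ah = integer(),
                                ak = integer(), al = integer(),
                                side = integer(), d = numeric(),
                                n = integer(), Im = numeric(),
                                Isd = numeric(), Iprop = numeric(),
                                sigma = numeric()),
                     dataset, list(config = config, nPatterns = 0L)))
  state <- .stateInit(dataset)
  if (!is.null(scales)) {
    i <- match(state$id, scales$id)
    state$s <- exp(scales$logScale[i])
    state$b <- scales$bFactor[i]
  }
  if (!is.null(radii)) state$R <- radii$profileRadius[match(state$id, radii$id)]
  g <- .mcMergeCorrected(.corrected(dt, state, config),
                         config$minMeasurements)
  .asMerged(g, dataset, list(config = config,
                             nPatterns = nrow(dataset@crystals),
                             nObs = nrow(dt)))
}

#' Full merging pipeline
#'
#' Runs the complete Monte Carlo merging pipeline: initial merge as
#' reference, `iterations` cycles of per-crystal scaling (and, under
#' "xsphere", partiality post-refinement) each followed by a re-merge,
#' then the per-crystal resolution push, outlier rejection and the final
#' merge.
#'
#' @param dataset a [StillDataset-class]
#' @param config a [mergeConfig()]
#' @param state optional starting state (data.frame id, s, b, R) overriding
#'   scale 1 / B 0 / stored radii
#' @return a [MergedDataset-class]
#' @export
runMerge <- function(dataset, config = mergeConfig(), state = NULL) {
  dt <- .mergePrep(dataset)
  if (!nrow(dt)) stop("dataset has no observations to merge")
  st <- .stateInit(dataset)
  if (!is.null(state)) {
    i <- match(st$id, state$id)
    if ("s" %in% names(state)) st$s <- state$s[i]
    if ("b" %in% names(state)) st$b <- state$b[i]
    if ("R" %in% names(state)) st$R <- state$R[i]
  }
  refG <- .mcMergeCorrected(.corrected(dt, st, config), 1L)
  for (it in seq_len(config$iterations)) {
    st <- .scaleState(dt, refG, st, config)
    if (config$model == "xsphere")
      st <- .postrefineState(dt, refG, st, config)
    refG <- .mcMergeCorrected(.corrected(dt, st, config), 1L)
  }
  cdt <- .corrected(dt, st, config)
  cdt <- .applyPushResDT(cdt, config$pushRes)
  cdt <- .rejectOutliersDT(cdt, config$outlierNsigma)
  g <- .mcMergeCorrected(cdt, config$minMeasurements)
  .asMerged(g, dataset,
            list(config = config, nPatterns = nrow(dataset@crystals),
                 nObs = nrow(dataset@observations), state = st))
}
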