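# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is mandatory for synthetic generation")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Specification of a synthetic CT phantom
#'
#' Describes a voxel phantom with an anatomical segment label map and a
#' controlled tissue-class mixture per segment. The right lung is partitioned
#' into its 10 segments (S1-S3 upper lobe), the left lung is a single bulk
#' region used only as a whole-lung denominator; a background margin of label
#' 0 surrounds the lungs. Each lung voxel draws a tissue class from the
#' segment's mixture weights and then an HU value from that class's normal
#' component: well-aerated N(-750, 40), emphysematous N(-950, 20),
#' non-aerated N(-200, 50).
#'
#' @param shape grid dimensions; default `c(64, 64, 60)`.
#' @param spacing voxel edge lengths in mm; default 1 mm isotropic.
#' @param weights mixture weights `(well_aerated, emphysematous, non_aerated)`
#'   — either one length-3 vector applied to every segment or a matrix with
#'   one row per segment (rownames = label codes). Rows must sum to 1.
#'   Default `c(0.80, 0.08, 0.12)`, a mostly healthy lung.
#' @param seed mandatory integer seed.
#' @param margin background border width in voxels; default 2.
#' @param components list of `c(mean, sd)` HU components named
#'   `well_aerated`, `emphysematous`, `non_aerated`.
#' @param table segment label table; default [default_segment_table()].
#' @param blocks optional custom geometry: named list (names = label codes) of
#'   lists with integer index ranges `x`, `y`, `z` (`c(lo, hi)`). Blocks must
#'   be disjoint; overlap is rejected. When `NULL` a default slab partition
#'   is built.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 60), spacing = c(1, 1, 1),
                         weights = c(0.80, 0.08, 0.12), seed,
                         margin = 2,
                         components = list(well_aerated = c(-750, 40),
                                           emphysematous = c(-950, 20),
                                           non_aerated = c(-200, 50)),
                         table = default_segment_table(), blocks = NULL) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L), all(spacing > 0))
  codes <- table$code
  if (is.null(dim(weights))) {
    stopifnot(length(weights) == 3L)
    weights <- matrix(rep(weights, each = length(codes)), ncol = 3L,
                      dimnames = list(codes, names(TISSUE_CLASSES)))
  } else {
    weights <- as.matrix(weights)
    stopifnot(ncol(weights) == 3L, nrow(weights) == length(codes))
    if (is.null(rownames(weights))) rownames(weights) <- codes
    colnames(weights) <- names(TISSUE_CLASSES)
  }
  if (any(weights < 0) || any(abs(rowSums(weights) - 1) > 1e-8))
    stop("per-segment mixture weights must be non-negative and sum to 1")
  stopifnot(all(c("well_aerated", "emphysematous", "non_aerated") %in%
                  names(components)))
  structure(list(shape = shape, spacing = as.double(spacing),
                 weights = weights, seed = as.integer(seed),
                 margin = as.integer(margin), components = components,
                 table = table, blocks = blocks),
            class = "phantom_spec")
}

# default geometry: interior split into left bulk (last code) and right
# slabs along z (first 10 codes)
default_phantom_blocks <- function(shape, margin, table) {
  lo <- rep(margin + 1L, 3L)
  hi <- shape - margin
  if (any(hi < lo)) stop("margin leaves no lung interior")
  right <- table$code[table$laterality == "right"]
  left <- table$code[table$laterality == "left"]
  x_split <- lo[1] + (hi[1] - lo[1]) %/% 2L
  blocks <- list()
  nz <- hi[3] - lo[3] + 1L
  edges <- lo[3] + round(seq(0, nz, length.out = length(right) + 1L))
  for (i in seq_along(right)) {
    if (edges[i + 1L] - 1L < edges[i]) stop("grid too small for 10 right-lung slabs")
    blocks[[as.character(right[i])]] <-
      list(x = c(x_split + 1L, hi[1]), y = c(lo[2], hi[2]),
           z = c(edges[i], edges[i + 1L] - 1L))
  }
  for (cd in left)
    blocks[[as.character(cd)]] <-
      list(x = c(lo[1], x_split), y = c(lo[2], hi[2]), z = c(lo[3], hi[3]))
  blocks
}

#' Generate a synthetic CT phantom
#'
#' Builds the label map from the spec's geometry, draws each lung voxel's
#' tissue class from the segment's mixture weights and its HU from the class
#' component distribution. Background voxels are set to -1024 HU. The
#' returned ground truth records the *realized* per-segment class fractions —
#' voxel counts after HU thresholding at the default thresholds — not the
#' target weights, so the phantom round-trips exactly through
#' [classify_volume()].
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([hu_volume()]), `labels` ([lung_label_map()])
#'   and `truth` (data.frame: `code`, `n_voxels`, `frac_well_aerated`,
#'   `frac_emphysematous`, `frac_non_aerated`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  blocks <- spec$blocks
  if (is.null(blocks))
    blocks <- default_phantom_blocks(spec$shape, spec$margin, spec$table)
  lab <- array(0L, dim = spec$shape)
  for (cd in names(blocks)) {
    b <- blocks[[cd]]
    xr <- b$x[1]:b$x[2]; yr <- b$y[1]:b$y[2]; zr <- b$z[1]:b$z[2]
    if (any(lab[xr, yr, zr] != 0L))
      stop("overlapping segment geometry at code ", cd)
    lab[xr, yr, zr] <- as.integer(cd)
  }
  # drop table rows for codes without geometry so map invariants hold
  table <- spec$table[spec$table$code %in% as.integer(names(blocks)), , drop = FALSE]
  labels <- lung_label_map(lab, table)

  hu <- array(-1024, dim = spec$shape)
  comp <- spec$components
  with_seed(spec$seed, {
    for (cd in table$code) {
      vox <- which(lab == cd)
      w <- spec$weights[as.character(cd), ]
      cls <- sample.int(3L, length(vox), replace = TRUE, prob = w)
      vals <- numeric(length(vox))
      # components truncated to their class windows so the drawn class is
      # the classified class (boundary leakage would otherwise blur tiny
      # tails of N(-750, 40) etc. across the thresholds)
      windows <- list(c(-900, -501), c(-1500, -900), c(-501, 200))
      for (k in 1:3) {
        sel <- cls == k
        if (any(sel)) {
          cm <- comp[[names(TISSUE_CLASSES)[k]]]
          vals[sel] <- rtrunc_norm(sum(sel), cm[1], cm[2],
                                   windows[[k]][1], windows[[k]][2])
        }
      }
      hu[vox] <- vals
    }
  })
  vol <- hu_volume(hu, spacing = spec$spacing)

  # realized ground truth: thresholded counts, not target weights
  truth <- do.call(rbind, lapply(table$code, function(cd) {
    v <- hu[lab == cd]
    n <- length(v)
    n_emph <- sum(v < -900)
    n_non <- sum(v > -501)
    n_well <- n - n_emph - n_non
    data.frame(code = cd, n_voxels = n,
               frac_well_aerated = n_well / n,
               frac_emphysematous = n_emph / n,
               frac_non_aerated = n_non / n)
  }))
  list(volume = vol, labels = labels, truth = truth)
}

#' Specification of a synthetic patient cohort
#'
#' Marginals emulate a right-upper-lobe resection cohort: age 68 (10) years,
#' preoperative FEV1 2.48 (0.59) L, FEV1/FVC 0.69 (0.09), DLCO 6.27 (1.99)
#' mmol/(min·kPa), RV 118 (25) % predicted, and a resected-segment mix of
#' 3 segments in 70%, 2 in 10% and 1 in 20% of patients. Marginals are drawn
#' independently (no joint distribution is imposed).
#'
#' The outcome model lets resection of predominantly non-functional tissue
#' *raise* postoperative FEV1: with `nf` the resected-region non-functional
#' fraction (Beta, mean 0.18) and `rff` the removed functional fraction
#' derived from the segment count and `nf`,
#' \deqn{FEV1_{post} = FEV1_{pre} (1 - rff)(1 + \gamma\, nf\, RV\%/100) +
#'   N(0, \sigma)}
#' Postoperative RV falls proportionally to the resected non-functional
#' volume. Defaults `gamma = 0.68` and `sigma = 0.15` L were chosen by moment
#' matching a mean postoperative/preoperative FEV1 ratio of 0.95 with a
#' change SD near 9% of the preoperative mean.
#'
#' @param n cohort size; default 20.
#' @param seed integer seed; default 1.
#' @param gamma compensation gain of the outcome model (0 disables it).
#' @param sigma measurement/biological noise SD on postoperative FEV1 (L).
#' @param seg_probs named probabilities of removing 3/2/1 segments.
#' @param nonfunc_beta `c(shape1, shape2)` of the resected-region
#'   non-functional fraction; default mean 0.18.
#' @param segment_share fraction of total lung volume per resected segment;
#'   default 0.0688 (2.5 segments ~ 17.2% of the lung).
#' @param marginals named list overriding marginal parameters (see Details in
#'   the source; each entry is `c(mean, sd)` plus truncation bounds).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 20, seed = 1, gamma = 0.68, sigma = 0.15,
                        seg_probs = c("3" = 0.70, "2" = 0.10, "1" = 0.20),
                        nonfunc_beta = c(shape1 = 2, shape2 = 9.111),
                        segment_share = 0.0688,
                        marginals = list()) {
  stopifnot(n >= 1, sigma >= 0, segment_share > 0,
            all(seg_probs >= 0), abs(sum(seg_probs) - 1) < 1e-8,
            all(nonfunc_beta > 0))
  defaults <- list(
    age      = c(mean = 68,   sd = 10,   lo = 40,  hi = 90),
    fev1     = c(mean = 2.48, sd = 0.59, lo = 0.8, hi = Inf),
    fev1_pct = c(mean = 92,   sd = 15,   lo = 40,  hi = 140),
    fev1_fvc = c(mean = 0.69, sd = 0.09, lo = 0.3, hi = 0.95),
    dlco     = c(mean = 6.27, sd = 1.99, lo = 1,   hi = Inf),
    dlco_pct = c(mean = 81,   sd = 22,   lo = 20,  hi = 160),
    rv_pct   = c(mean = 118,  sd = 25,   lo = 60,  hi = 200),
    bmi      = c(mean = 27,   sd = 4.9,  lo = 16,  hi = 45),
    healthy  = c(mean = 0.83, sd = 0.12, lo = 0.40, hi = 0.99)
  )
  for (nm in names(marginals)) {
    if (!nm %in% names(defaults)) stop("unknown marginal: ", nm)
    defaults[[nm]][names(marginals[[nm]])] <- marginals[[nm]]
  }
  structure(list(n = as.integer(n), seed = as.integer(seed), gamma = gamma,
                 sigma = sigma, seg_probs = seg_probs,
                 nonfunc_beta = nonfunc_beta, segment_share = segment_share,
                 marginals = defaults),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws patient records under a [cohort_spec()] and applies the outcome
#' model described there. Ground-truth generator quantities travel in
#' `truth_`-prefixed columns, including the response flag
#' `truth_response = (postoperative FEV1 > preoperative FEV1)`.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of class `ppolung_cohort`, one row per patient.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  m <- spec$marginals
  draw <- function(nm) rtrunc_norm(n, m[[nm]][["mean"]], m[[nm]][["sd"]],
                                   m[[nm]][["lo"]], m[[nm]][["hi"]])
  with_seed(spec$seed, {
    age <- draw("age")
    sex <- sample(c("F", "M"), n, replace = TRUE)
    bmi <- draw("bmi")
    fev1 <- draw("fev1")
    fev1_pct <- draw("fev1_pct")
    fev1_fvc <- draw("fev1_fvc")
    dlco <- draw("dlco")
    dlco_pct <- draw("dlco_pct")
    rv_pct <- draw("rv_pct")
    rv_l <- 2.2 * rv_pct / 100   # ~2.2 L predicted residual volume

    k <- as.integer(sample(names(spec$seg_probs), n, replace = TRUE,
                           prob = spec$seg_probs))
    rul <- c("S1", "S2", "S3")
    segs <- vapply(k, function(ki)
      paste(sort(sample(rul, ki)), collapse = ";"), "")

    nf <- stats::rbeta(n, spec$nonfunc_beta[[1]], spec$nonfunc_beta[[2]])
    healthy <- draw("healthy")
    removed_total <- k * spec$segment_share
    rff <- pmin(removed_total * (1 - nf) / healthy, 1)

    gain <- 1 + spec$gamma * nf * rv_pct / 100
    noise <- if (spec$sigma > 0) stats::rnorm(n, 0, spec$sigma) else 0
    fev1_post <- pmax(fev1 * (1 - rff) * gain + noise, 0.1)

    dlco_noise <- if (spec$sigma > 0) stats::rnorm(n, 0, 2.5 * spec$sigma) else 0
    dlco_post <- pmax(dlco * (1 - 0.5 * rff) + dlco_noise, 0.3)

    # RV falls with the resected non-functional (hyperinflated) volume
    rv_post <- rv_l * pmax(1 - removed_total * (0.4 + 1.5 * nf), 0.5)

    out <- data.frame(
      id = sprintf("P%03d", seq_len(n)),
      age = age, sex = sex, bmi = bmi,
      segments_removed = k, resected_segments = segs,
      preop_fev1_l = fev1, preop_fev1_pct = fev1_pct,
      preop_fev1_fvc = fev1_fvc, preop_dlco = dlco,
      preop_dlco_pct = dlco_pct, preop_rv_l = rv_l, preop_rv_pct = rv_pct,
      postop_fev1_l = fev1_post,
      postop_fev1_pct = fev1_pct * fev1_post / fev1,
      postop_dlco = dlco_post,
      postop_dlco_pct = dlco_pct * dlco_post / dlco,
      postop_rv_l = rv_post,
      postop_rv_pct = rv_pct * rv_post / rv_l,
      truth_removed_total_fraction = removed_total,
      truth_removed_functional_fraction = rff,
      truth_healthy_over_total = healthy,
      truth_removed_healthy_over_removed_total = 1 - nf,
      truth_nonfunctional_fraction = nf,
      truth_response = fev1_post > fev1,
      stringsAsFactors = FALSE
    )
    class(out) <- c("ppolung_cohort", "data.frame")
    out
  })
}
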