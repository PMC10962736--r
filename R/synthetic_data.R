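# Synthetic fixtures with machine-readable planted truth. Expression
# fixtures emulate the three-arm factorial design (control; stress with the
# modifier intact; stress with the modifier knocked out): the planted
# stress-arm mean is baseline + beta and the planted KO-arm mean is
# baseline + beta * (1 - dependence_pct/100), with i.i.d. Gaussian replicate
# noise on the log2 scale. Mask fixtures rasterize planted ellipses; fiber
# fixtures tessellate planted per-group areas and intensities exactly.

#' Per-gene generative plan
#'
#' @param gene_id Gene identifier (unique within a model).
#' @param baseline Control-arm mean, log2 units.
#' @param beta Planted stress log2 fold change (stress/modifier+ arm vs
#'   control arm).
#' @param dependence_pct Fraction of `beta` reverted in the KO arm, percent
#'   (0-150; values over 100 model overshoot).
#' @param noise_sd Replicate noise SD, log2 units (>= 0).
#' @return One-row data.frame.
#' @export
gene_plan <- function(gene_id, baseline = 8, beta = 0, dependence_pct = 0,
                      noise_sd = 0.1) {
  data.frame(gene_id = gene_id, baseline = baseline, beta = beta,
             dependence_pct = dependence_pct, noise_sd = noise_sd,
             stringsAsFactors = FALSE)
}

#' Fixture specification for a factorial expression fixture
#'
#' @param plans data.frame with columns `model`, `gene_id`, `baseline`,
#'   `beta`, `dependence_pct`, `noise_sd`; every model must define every
#'   gene.
#' @param n_per_arm Replicates per arm (>= 2).
#' @param seed Integer seed; identical (spec, seed) reproduces identical
#'   output.
#' @param noiseless Zero out all replicate noise.
#' @param fc_threshold,fdr_threshold Thresholds used to derive the expected
#'   truth flags from the planted means.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(plans, n_per_arm = 6, seed = 1, noiseless = FALSE,
                         fc_threshold = 2, fdr_threshold = 0.05) {
  need <- c("model", "gene_id", "baseline", "beta", "dependence_pct", "noise_sd")
  if (!all(need %in% names(plans))) {
    validation_error("plans must have columns: %s", paste(need, collapse = ", "))
  }
  if (n_per_arm < 2) validation_error("n_per_arm must be >= 2 (sample variance)")
  if (any(plans$noise_sd < 0)) validation_error("noise_sd must be >= 0")
  if (any(plans$dependence_pct < 0 | plans$dependence_pct > 150)) {
    validation_error("dependence_pct must lie in [0, 150]")
  }
  for (m in unique(plans$model)) {
    g <- plans$gene_id[plans$model == m]
    if (anyDuplicated(g)) {
      validation_error("duplicate gene ids in model '%s': %s", m,
                       paste(unique(g[duplicated(g)]), collapse = ", "))
    }
  }
  genes <- unique(plans$gene_id)
  for (m in unique(plans$model)) {
    miss <- setdiff(genes, plans$gene_id[plans$model == m])
    if (length(miss)) {
      validation_error("model '%s' lacks plans for %d gene(s)", m, length(miss))
    }
  }
  structure(list(plans = plans, n_per_arm = as.integer(n_per_arm),
                 seed = as.integer(seed), noiseless = isTRUE(noiseless),
                 fc_threshold = fc_threshold, fdr_threshold = fdr_threshold),
            class = "fixture_spec")
}

#' Generate a factorial expression fixture with planted truth
#'
#' For each model, three arms of `n_per_arm` samples (control, stress with
#' modifier intact, stress with modifier KO) with per-gene planted means and
#' i.i.d. normal log2 noise. The truth table carries, per model and gene,
#' the planted effect and dependence plus the expected DEG/dependence flags
#' implied by the planted means under the configured thresholds (noise never
#' enters the expectations).
#'
#' @param spec A [fixture_spec()].
#' @return List with `matrix` (genes x samples log2 expression), `samples`
#'   (sample sheet: `sample_id`, `model`, `arm`, `stress`, `genotype`,
#'   `replicate`), `truth` (model, gene_id, beta, dependence_pct,
#'   expected_deg, expected_dependent).
#' @export
generate_expression_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  plans <- spec$plans
  models <- unique(plans$model)
  genes <- unique(plans$gene_id)
  arms <- c("control", "stress_wt", "stress_ko")
  n <- spec$n_per_arm

  samples <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(arms, function(a) {
      data.frame(sample_id = sprintf("%s_%s_r%d", m, a, seq_len(n)),
                 model = m, arm = a,
                 stress = a != "control",
                 genotype = if (a == "stress_ko") "ko" else "wt",
                 replicate = seq_len(n), stringsAsFactors = FALSE)
    }))
  }))

  mat <- matrix(NA_real_, nrow = length(genes), ncol = nrow(samples),
                dimnames = list(genes, samples$sample_id))
  with_seed(spec$seed, {
    for (m in models) {
      pm <- plans[plans$model == m, ]
      pm <- pm[match(genes, pm$gene_id), ]
      means <- cbind(control = pm$baseline,
                     stress_wt = pm$baseline + pm$beta,
                     stress_ko = pm$baseline + pm$beta * (1 - pm$dependence_pct / 100))
      for (a in arms) {
        cols <- samples$sample_id[samples$model == m & samples$arm == a]
        noise <- if (spec$noiseless) 0 else {
          matrix(stats::rnorm(length(genes) * n), length(genes), n) * pm$noise_sd
        }
        mat[, cols] <- means[, a] + noise
      }
    }
  })

  lfc_cut <- log2(spec$fc_threshold)
  truth <- plans[, c("model", "gene_id", "beta", "dependence_pct")]
  truth$expected_deg <- abs(truth$beta) >= lfc_cut
  truth$expected_dependent <- truth$expected_deg &
    truth$dependence_pct > 0 &
    abs(truth$beta * truth$dependence_pct / 100) >= lfc_cut
  rownames(truth) <- NULL

  list(matrix = mat, samples = samples, truth = truth)
}

# ---------------------------------------------------------------------------
# Expression presets. Planted effects sit >= 3 standard errors of the
# estimated log2 fold change from every decision boundary (the |log2FC| >= 1
# gates on both contrasts and the 50% dependence cutoff), so recovery is
# robust to the seed.

heart_core_gene_ids <- function() {
  c("Phgdh", "Psat1", "Pycr1", "Asns", "Pck2", "Slc7a11", "Slc7a1", "Fgf21",
    "Mthfd2", "Chac1", "Shmt2", sprintf("core_%02d", 12:51))
}

#' Three-model heart fixture preset
#'
#' Plants, across three cardiomyopathy/myopathy-like models, a shared
#' direction-consistent stress-DEG set of 111 genes of which 51 are
#' dependent in all three models (85% dependence), 6 pass the 50%
#' dependence cutoff without meeting the strict significance-plus-reversion
#' criterion (68% dependence with a KO fold change under the gate), and 54
#' are weakly dependent (20%); 39 further genes are dependent in exactly two
#' of the three models; each model additionally carries 123 model-specific
#' non-dependent DEGs, and 500 null genes are shared.
#'
#' @param seed Integer seed.
#' @param n_per_arm Replicates per arm (default 6).
#' @param noise_sd Replicate noise SD, log2 units (default 0.1).
#' @param noiseless Zero noise.
#' @return A [fixture_spec()].
#' @export
preset_heart_threemodel <- function(seed = 1, n_per_arm = 6, noise_sd = 0.1,
                                    noiseless = FALSE) {
  models <- c("g58r", "s59l", "tfam")
  core <- heart_core_gene_ids()
  core_beta <- ifelse(seq_along(core) <= 34, 2, -2)
  near <- sprintf("near_%02d", 1:6)
  near_beta <- ifelse(1:6 <= 4, 1.2, -1.2)
  low <- sprintf("low_%02d", 1:54)
  low_beta <- ifelse(1:54 <= 40, 2, -2)
  pair <- sprintf("pair_%02d", 1:39)
  pair_member <- list(c("g58r", "s59l"), c("s59l", "tfam"), c("g58r", "tfam"))
  pair_models <- pair_member[((seq_along(pair) - 1) %% 3) + 1]
  nulls <- sprintf("null_%03d", 1:500)

  rows <- list()
  for (m in models) {
    uniq <- sprintf("uniq_%s_%03d", m, 1:123)
    for (mm in models) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = mm, gene_id = uniq,
        beta = if (mm == m) rep(c(2, -2), length.out = 123) else 0,
        dependence_pct = 0, stringsAsFactors = FALSE)
    }
  }
  for (m in models) {
    pair_in <- vapply(pair_models, function(p) m %in% p, logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      model = m,
      gene_id = c(core, near, low, pair, nulls),
      beta = c(core_beta, near_beta, low_beta,
               ifelse(pair_in, 2, 0), rep(0, length(nulls))),
      dependence_pct = c(rep(85, length(core)), rep(68, length(near)),
                         rep(20, length(low)), ifelse(pair_in, 85, 0),
                         rep(0, length(nulls))),
      stringsAsFactors = FALSE)
  }
  plans <- do.call(rbind, rows)
  genes <- unique(plans$gene_id)
  base <- 6 + 6 * (match(plans$gene_id, genes) %% 37) / 37
  plans$baseline <- base
  plans$noise_sd <- noise_sd
  fixture_spec(plans, n_per_arm = n_per_arm, seed = seed, noiseless = noiseless)
}

#' Brown-adipose cold-stress fixture preset
#'
#' Single-tissue three-arm design with 7 replicates per arm. Plants 11
#' dependent genes (named after canonical integrated-stress-response
#' transcripts) with dependence values spanning 70-97%, 25 stress DEGs with
#' weak (20%) dependence, and 400 null genes.
#'
#' @inheritParams preset_heart_threemodel
#' @param n_per_arm Replicates per arm (default 7).
#' @return A [fixture_spec()].
#' @export
preset_bat_coldstress <- function(seed = 1, n_per_arm = 7, noise_sd = 0.1,
                                  noiseless = FALSE) {
  dep_genes <- c("Mthfd2", "Cth", "Fgf21", "Chac1", "Psat1", "Slc7a1",
                 "Slc7a5", "Cars", "Tars", "Pycr1", "Asns")
  dep_vals <- c(97, 95, 93, 90, 88, 86, 83, 80, 77, 74, 70)
  degs <- sprintf("bat_deg_%02d", 1:25)
  nulls <- sprintf("bat_null_%03d", 1:400)
  plans <- data.frame(
    model = "bat",
    gene_id = c(dep_genes, degs, nulls),
    beta = c(rep(2.2, length(dep_genes)), rep(c(2, -2), length.out = 25),
             rep(0, length(nulls))),
    dependence_pct = c(dep_vals, rep(20, 25), rep(0, length(nulls))),
    stringsAsFactors = FALSE)
  plans$baseline <- 6 + 6 * (seq_len(nrow(plans)) %% 31) / 31
  plans$noise_sd <- noise_sd
  fixture_spec(plans, n_per_arm = n_per_arm, seed = seed, noiseless = noiseless)
}

#' Gastrocnemius overlay fixture preset
#'
#' Skeletal-muscle fixture whose dependent set overlaps the heart core
#' signature of [preset_heart_threemodel()] in exactly 32 of its 51 genes;
#' the other 19 core genes are planted as sub-threshold trends (log2 fold
#' change 0.5). Adds 20 muscle-specific dependent genes, 30 non-dependent
#' DEGs, and 300 nulls.
#'
#' @inheritParams preset_heart_threemodel
#' @return A [fixture_spec()].
#' @export
preset_gastroc_overlay <- function(seed = 1, n_per_arm = 6, noise_sd = 0.1,
                                   noiseless = FALSE) {
  core <- heart_core_gene_ids()
  in_overlap <- seq_along(core) <= 32
  gas_dep <- sprintf("gas_dep_%02d", 1:20)
  degs <- sprintf("gas_deg_%02d", 1:30)
  nulls <- sprintf("gas_null_%03d", 1:300)
  plans <- data.frame(
    model = "gastroc",
    gene_id = c(core, gas_dep, degs, nulls),
    beta = c(ifelse(in_overlap, 2, 0.5), rep(2, 20),
             rep(c(2, -2), length.out = 30), rep(0, length(nulls))),
    dependence_pct = c(ifelse(in_overlap, 85, 0), rep(85, 20), rep(20, 30),
                       rep(0, length(nulls))),
    stringsAsFactors = FALSE)
  plans$baseline <- 6 + 6 * (seq_len(nrow(plans)) %% 29) / 29
  plans$noise_sd <- noise_sd
  fixture_spec(plans, n_per_arm = n_per_arm, seed = seed, noiseless = noiseless)
}

# ---------------------------------------------------------------------------
# Label-mask fixtures

#' Generate an ellipse label-mask fixture with planted geometry
#'
#' Rasterizes planted ellipses (pixel centers at integer coordinates) into
#' an integer label mask, background 0, labels 1..K in placement order.
#' Centers are drawn under the seed; overlaps are avoided by rejection
#' sampling on enclosing circles with bounded retries.
#'
#' @param shapes data.frame with columns `semi_major_px`, `semi_minor_px`,
#'   `rotation` (radians).
#' @param pixel_size_nm Physical pixel size, nm.
#' @param image_shape `c(rows, cols)`.
#' @param seed Integer seed.
#' @param max_retries Placement attempts per shape before failing.
#' @return List with `labels` (integer matrix) and `truth` (label,
#'   semi-axes px, `major_axis_nm`, `minor_axis_nm` (full axes),
#'   `area_um2` (analytic pi*a*b), `aspect_ratio`, `is_nano` under the
#'   nano rule).
#' @export
generate_mask_fixture <- function(shapes, pixel_size_nm, image_shape,
                                  seed = 1, max_retries = 1000L) {
  if (any(shapes$semi_minor_px <= 0) ||
      any(shapes$semi_major_px < shapes$semi_minor_px)) {
    validation_error("need semi_major_px >= semi_minor_px > 0")
  }
  if (pixel_size_nm <= 0) validation_error("pixel_size_nm must be > 0")
  h <- image_shape[1]; w <- image_shape[2]
  k <- nrow(shapes)
  labels <- matrix(0L, h, w)
  centers <- matrix(NA_real_, k, 2)
  radius <- shapes$semi_major_px

  with_seed(seed, {
    for (i in seq_len(k)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        cy <- stats::runif(1, radius[i] + 2, h - radius[i] - 1)
        cx <- stats::runif(1, radius[i] + 2, w - radius[i] - 1)
        if (i == 1L) ok <- TRUE else {
          prev <- seq_len(i - 1L)
          d <- sqrt((centers[prev, 1] - cy)^2 + (centers[prev, 2] - cx)^2)
          ok <- all(d > radius[prev] + radius[i] + 2)
        }
        if (ok) { centers[i, ] <- c(cy, cx); placed <- TRUE; break }
      }
      if (!placed) {
        stopf("could not place shape %d after %d retries", i, max_retries,
              class = "mtisr_placement_error")
      }
    }
  })

  for (i in seq_len(k)) {
    a <- shapes$semi_major_px[i]; b <- shapes$semi_minor_px[i]
    th <- shapes$rotation[i]
    cy <- centers[i, 1]; cx <- centers[i, 2]
    rr <- max(1L, floor(cy - a)):min(h, ceiling(cy + a))
    cc <- max(1L, floor(cx - a)):min(w, ceiling(cx + a))
    dy <- outer(rr - cy, rep(1, length(cc)))
    dx <- outer(rep(1, length(rr)), cc - cx)
    u <- dy * cos(th) + dx * sin(th)
    v <- -dy * sin(th) + dx * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    labels[rr, cc][inside] <- i
  }

  minor <- 2 * shapes$semi_minor_px * pixel_size_nm
  major <- 2 * shapes$semi_major_px * pixel_size_nm
  ar <- major / minor
  truth <- data.frame(
    label = seq_len(k),
    semi_major_px = shapes$semi_major_px,
    semi_minor_px = shapes$semi_minor_px,
    major_axis_nm = major, minor_axis_nm = minor, aspect_ratio = ar,
    area_um2 = pi * shapes$semi_major_px * shapes$semi_minor_px *
      (pixel_size_nm / 1000)^2,
    is_nano = classify_nano(minor, ar))
  list(labels = labels, truth = truth)
}

#' Ellipse-population preset with a planted 22% nano fraction
#'
#' 200 ellipses at 10 nm/pixel: 44 nano profiles (minor axis 160-200 nm,
#' aspect ratio 1.0-1.3), 100 large round profiles (minor axis 320-600 nm),
#' and 56 elongated tubule cross-cuts (aspect ratio 2.0-3.5). All planted
#' axes and ratios keep at least 20% clearance from the 250 nm and 1.5
#' decision boundaries so rasterization error (under 2%) cannot flip a
#' call.
#'
#' @param seed Integer seed.
#' @return List with `shapes` (planted ellipse table, shuffled order),
#'   `pixel_size_nm`, `image_shape`.
#' @export
preset_s59l_population <- function(seed = 1) {
  with_seed(seed, {
    nano <- data.frame(semi_minor_px = stats::runif(44, 8, 10),
                       ar = stats::runif(44, 1.0, 1.3))
    round_big <- data.frame(semi_minor_px = stats::runif(100, 16, 30),
                            ar = stats::runif(100, 1.0, 1.35))
    elong <- data.frame(semi_minor_px = stats::runif(56, 8, 11),
                        ar = stats::runif(56, 2.0, 3.5))
    shapes <- rbind(nano, round_big, elong)
    shapes$semi_major_px <- shapes$semi_minor_px * shapes$ar
    shapes$rotation <- stats::runif(nrow(shapes), 0, pi)
    shapes <- shapes[sample.int(nrow(shapes)), c("semi_major_px",
                                                 "semi_minor_px", "rotation")]
    rownames(shapes) <- NULL
    list(shapes = shapes, pixel_size_nm = 10, image_shape = c(2048L, 2048L))
  })
}

# ---------------------------------------------------------------------------
# Fiber fixtures

#' Generate a myofiber fixture with planted CSA and intensity
#'
#' Tessellates an image into contiguous raster runs, one per fiber, with
#' integer pixel counts chosen so each group's mean cross-sectional area
#' equals its planted mean exactly; per-fiber intensity is uniform over the
#' fiber (equal to the planted group mean in noiseless mode).
#'
#' @param n_fibers Named integer vector, fibers per group
#'   (`ub_pos`, `ub_neg`).
#' @param csa_mean_by_group Named numeric vector of planted mean CSAs, um^2;
#'   `mean * n` must be a whole pixel count for exact recovery.
#' @param intensity_mean_by_group Named numeric vector of planted mean
#'   intensities (positive).
#' @param pixel_size_nm Pixel size, nm (default 1000, i.e. 1 um^2 pixels).
#' @param seed Integer seed.
#' @param noiseless Exact planted intensities (default TRUE); otherwise 5%
#'   lognormal-free Gaussian jitter per fiber, truncated at zero.
#' @param width Image width in pixels.
#' @return List with `labels`, `intensity` (matrices), `truth` (label,
#'   group, csa_um2, intensity), `pixel_size_nm`, `annotations`
#'   (label, ub_status).
#' @export
generate_fiber_fixture <- function(n_fibers = c(ub_pos = 30, ub_neg = 30),
                                   csa_mean_by_group = c(ub_pos = 330.0,
                                                         ub_neg = 446.9),
                                   intensity_mean_by_group = c(ub_pos = 2712,
                                                               ub_neg = 1000),
                                   pixel_size_nm = 1000, seed = 1,
                                   noiseless = TRUE, width = 128L) {
  groups <- names(n_fibers)
  if (is.null(groups) || !setequal(names(csa_mean_by_group), groups) ||
      !setequal(names(intensity_mean_by_group), groups)) {
    validation_error("n_fibers, csa_mean_by_group, intensity_mean_by_group must share group names")
  }
  if (any(csa_mean_by_group <= 0) || any(intensity_mean_by_group <= 0)) {
    validation_error("planted group means must be positive")
  }
  px_area <- (pixel_size_nm / 1000)^2

  truth <- with_seed(seed, {
    rows <- lapply(groups, function(g) {
      n <- n_fibers[[g]]
      total_px <- csa_mean_by_group[[g]] * n / px_area
      if (abs(total_px - round(total_px)) > 1e-6) {
        warning(sprintf("group '%s': planted mean CSA not a whole pixel count per group; mean will be %.6g",
                        g, round(total_px) * px_area / n), call. = FALSE)
      }
      total_px <- round(total_px)
      base <- total_px %/% n
      counts <- rep(base, n) + c(rep(1L, total_px - base * n),
                                 rep(0L, n - (total_px - base * n)))
      jit <- round(stats::rnorm(n, 0, 0.15 * base))
      jit <- jit - round(mean(jit))
      jit[1] <- jit[1] - sum(jit)
      counts <- pmax(counts + jit, 1L)
      counts[1] <- counts[1] + (total_px - sum(counts))
      if (counts[1] < 1L) validation_error("fiber size adjustment failed; lower jitter")
      intens <- if (noiseless) rep(intensity_mean_by_group[[g]], n) else {
        pmax(stats::rnorm(n, intensity_mean_by_group[[g]],
                          0.05 * intensity_mean_by_group[[g]]), 0)
      }
      data.frame(group = g, n_pixels = counts, intensity = intens,
                 stringsAsFactors = FALSE)
    })
    tr <- do.call(rbind, rows)
    tr <- tr[sample.int(nrow(tr)), ]
    tr$label <- seq_len(nrow(tr))
    tr
  })
  truth$csa_um2 <- truth$n_pixels * px_area

  total <- sum(truth$n_pixels)
  h <- ceiling(total / width)
  v <- c(rep(truth$label, truth$n_pixels), rep(0L, h * width - total))
  labels <- matrix(v, nrow = h, ncol = width, byrow = TRUE)
  intensity <- matrix(0, h, width)
  idx <- labels > 0
  intensity[idx] <- truth$intensity[match(labels[idx], truth$label)]

  rownames(truth) <- NULL
  list(labels = labels, intensity = intensity,
       truth = truth[, c("label", "group", "csa_um2", "intensity")],
       pixel_size_nm = pixel_size_nm,
       annotations = data.frame(label = truth$label,
                                ub_status = sub("^ub_", "", truth$group),
                                stringsAsFactors = FALSE))
}
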