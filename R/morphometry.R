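# Rule-based morphometry on instance-segmentation label masks: per-label
# equivalent-ellipse shape features, the nano-mitochondrion rule, population
# summaries with annotation frequencies, and per-fiber CSA / intensity
# quantification.
#
# Conventions (fixed, and used by the planted-truth generators): pixel
# centers sit at integer coordinates; area = pixel count (no boundary
# correction); axis length = 4 * sqrt(eigenvalue of the 2x2 second-central-
# moment matrix of member pixel coordinates) -- the full axis of the
# equivalent ellipse, as in common region-properties implementations.

#' Per-label equivalent-ellipse features
#'
#' For every label in an integer mask (0 = background), computes the area in
#' um^2 and the major/minor axis lengths in nm from the eigenvalues of the
#' second central moment matrix of member pixel coordinates. Labels of fewer
#' than 4 pixels are emitted with a `degenerate` flag (axes computed but
#' unreliable). Each label is optionally checked to form one 8-connected
#' component; violations are flagged via the `connected` column and a
#' warning, not an error.
#'
#' @param labels Integer matrix, 0 background, positive labels.
#' @param pixel_size_nm Physical pixel size in nm (> 0).
#' @param check_connectivity Verify 8-connectivity per label (default TRUE).
#' @return data.frame with `label`, `n_pixels`, `area_um2`, `major_axis_nm`,
#'   `minor_axis_nm`, `aspect_ratio`, `degenerate`, `connected`, sorted by
#'   label.
#' @export
region_features <- function(labels, pixel_size_nm, check_connectivity = TRUE) {
  if (!is.matrix(labels) || any(labels < 0)) {
    validation_error("labels must be a non-negative integer matrix")
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    validation_error("pixel_size_nm must be > 0")
  }
  idx <- which(labels > 0)
  if (!length(idx)) {
    return(data.frame(label = integer(), n_pixels = integer(),
                      area_um2 = numeric(), major_axis_nm = numeric(),
                      minor_axis_nm = numeric(), aspect_ratio = numeric(),
                      degenerate = logical(), connected = logical()))
  }
  lab <- labels[idx]
  rc <- arrayInd(idx, dim(labels))
  r <- rc[, 1]; c <- rc[, 2]
  f <- factor(lab)
  n <- as.vector(table(f))
  sr <- rowsum(r, f); sc <- rowsum(c, f)
  mr <- sr / n; mc <- sc / n
  # central second moments per label (covariance of pixel coordinates)
  g <- as.integer(f)
  dr <- r - mr[g]; dc <- c - mc[g]
  mu20 <- rowsum(dr * dr, f) / n
  mu02 <- rowsum(dc * dc, f) / n
  mu11 <- rowsum(dr * dc, f) / n
  tr2 <- (mu20 + mu02) / 2
  det_root <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- pmax(tr2 + det_root, 0)
  l2 <- pmax(tr2 - det_root, 0)
  major <- 4 * sqrt(l1) * pixel_size_nm
  minor <- 4 * sqrt(l2) * pixel_size_nm

  connected <- rep(TRUE, nlevels(f))
  if (check_connectivity) {
    for (i in seq_len(nlevels(f))) {
      sel <- g == i
      connected[i] <- is_one_component(r[sel], c[sel])
    }
    if (any(!connected)) {
      warning(sprintf("labels not 8-connected: %s",
                      paste(levels(f)[!connected], collapse = ", ")),
              call. = FALSE)
    }
  }

  data.frame(label = as.integer(levels(f)), n_pixels = n,
             area_um2 = n * (pixel_size_nm / 1000)^2,
             major_axis_nm = as.vector(major),
             minor_axis_nm = as.vector(minor),
             aspect_ratio = as.vector(ifelse(minor > 0, major / minor, Inf)),
             degenerate = n < 4L, connected = connected,
             row.names = NULL)
}

# BFS flood fill over one label's pixel set; TRUE if a single 8-connected
# component.
is_one_component <- function(r, c) {
  n <- length(r)
  if (n <= 1L) return(TRUE)
  r0 <- r - min(r) + 1L; c0 <- c - min(c) + 1L
  h <- max(r0); w <- max(c0)
  occ <- matrix(FALSE, h, w)
  occ[cbind(r0, c0)] <- TRUE
  seen <- matrix(FALSE, h, w)
  queue <- c(r0[1], c0[1])
  seen[r0[1], c0[1]] <- TRUE
  count <- 0L
  while (length(queue)) {
    cr <- queue[1]; cc <- queue[2]; queue <- queue[-(1:2)]
    count <- count + 1L
    for (dr in -1:1) for (dc in -1:1) {
      nr <- cr + dr; nc <- cc + dc
      if (nr >= 1L && nr <= h && nc >= 1L && nc <= w &&
          occ[nr, nc] && !seen[nr, nc]) {
        seen[nr, nc] <- TRUE
        queue <- c(queue, nr, nc)
      }
    }
  }
  count == n
}

#' Nano-mitochondrion rule
#'
#' A segmented mitochondrial profile is "nano" when its minor axis is under
#' 250 nm and its aspect ratio is under 1.5 (both strict), i.e. a small,
#' near-round profile rather than a thin tubule cross-cut.
#'
#' @param minor_axis_nm Minor axis length(s), nm, or a [region_features()]
#'   table (then `aspect_ratio` is taken from it).
#' @param aspect_ratio Aspect ratio(s) (major/minor).
#' @return Logical vector.
#' @export
classify_nano <- function(minor_axis_nm, aspect_ratio = NULL) {
  if (is.data.frame(minor_axis_nm)) {
    aspect_ratio <- minor_axis_nm$aspect_ratio
    minor_axis_nm <- minor_axis_nm$minor_axis_nm
  }
  minor_axis_nm < 250 & aspect_ratio < 1.5
}

#' Population summary of mitochondrial morphometry
#'
#' Tabulates n, median and IQR of area and aspect ratio, the rule-based nano
#' frequency, and the frequency of any user-supplied manual ultrastructural
#' classes (e.g. cristal inclusion, electrolucent), as percents of the
#' population.
#'
#' @param records [region_features()] table (a `nano` column is added if
#'   absent).
#' @param annotations Optional data.frame with columns `label`, `class`;
#'   every annotated label must exist in `records`. A label may carry
#'   several classes.
#' @return List with `summary` (one-row data.frame: `n`, `median_area_um2`,
#'   `iqr_area_um2`, `median_aspect_ratio`, `iqr_aspect_ratio`, `pct_nano`)
#'   and `class_freq` (data.frame `class`, `n`, `pct` over all rule-based
#'   and manual classes).
#' @export
summarize_population <- function(records, annotations = NULL) {
  if (!nrow(records)) validation_error("empty record table")
  nano <- if ("nano" %in% names(records)) records$nano else classify_nano(records)
  n <- nrow(records)
  classes <- data.frame(class = "nano", n = sum(nano),
                        pct = 100 * sum(nano) / n, stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(annotations)) {
    unknown <- setdiff(annotations$label, records$label)
    if (length(unknown)) {
      contract_error("annotation labels absent from mask: %s",
                     paste(utils::head(unknown, 10), collapse = ", "))
    }
    counts <- table(annotations$class)
    classes <- rbind(classes,
                     data.frame(class = names(counts), n = as.vector(counts),
                                pct = 100 * as.vector(counts) / n,
                                stringsAsFactors = FALSE))
  }
  summary <- data.frame(
    n = n,
    median_area_um2 = stats::median(records$area_um2),
    iqr_area_um2 = stats::IQR(records$area_um2),
    median_aspect_ratio = stats::median(records$aspect_ratio),
    iqr_aspect_ratio = stats::IQR(records$aspect_ratio),
    pct_nano = 100 * sum(nano) / n)
  list(summary = summary, class_freq = classes)
}

#' Per-fiber cross-sectional area and mean intensity
#'
#' @param labels Integer fiber mask (0 = background).
#' @param intensity Numeric matrix, same shape as `labels`.
#' @param pixel_size_nm Physical pixel size in nm.
#' @param ub_annotations Optional data.frame `label`, `ub_status`
#'   (`"pos"`/`"neg"`); unannotated fibers get `NA` status.
#' @return data.frame with `label`, `csa_um2`, `mean_intensity`,
#'   `ub_status`.
#' @export
fiber_quantify <- function(labels, intensity, pixel_size_nm,
                           ub_annotations = NULL) {
  if (!identical(dim(labels), dim(intensity))) {
    contract_error("intensity image shape %s does not match mask shape %s",
                   paste(dim(intensity), collapse = "x"),
                   paste(dim(labels), collapse = "x"))
  }
  if (pixel_size_nm <= 0) validation_error("pixel_size_nm must be > 0")
  idx <- which(labels > 0)
  f <- factor(labels[idx])
  n <- as.vector(table(f))
  mean_int <- as.vector(rowsum(as.numeric(intensity[idx]), f)) / n
  out <- data.frame(label = as.integer(levels(f)),
                    csa_um2 = n * (pixel_size_nm / 1000)^2,
                    mean_intensity = mean_int,
                    ub_status = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(ub_annotations) && nrow(ub_annotations)) {
    m <- match(out$label, ub_annotations$label)
    out$ub_status <- ub_annotations$ub_status[m]
  }
  out
}

#' Percent difference of group means (aggregate-positive vs -negative)
#'
#' `100 * (mean_pos - mean_neg) / mean_neg` over fibers with known
#' `ub_status`; fibers without a status are excluded and counted in the
#' attached attribute `n_unannotated`.
#'
#' @param records [fiber_quantify()] table with `ub_status`.
#' @param field `"mean_intensity"` or `"csa_um2"`.
#' @return Percent difference (scalar), `NA` with a warning if either group
#'   is empty or the negative-group mean is zero.
#' @export
group_percent_difference <- function(records,
                                     field = c("mean_intensity", "csa_um2")) {
  field <- match.arg(field)
  pos <- records[[field]][records$ub_status %in% "pos"]
  neg <- records[[field]][records$ub_status %in% "neg"]
  out <- if (!length(pos) || !length(neg) || mean(neg) == 0) {
    warning("percent difference undefined (empty group or zero denominator)",
            call. = FALSE)
    NA_real_
  } else {
    100 * (mean(pos) - mean(neg)) / mean(neg)
  }
  attr(out, "n_unannotated") <- sum(is.na(records$ub_status))
  out
}
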