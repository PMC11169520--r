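#' Run the fluorescence-guided quantification workflow
#'
#' For each triplet: normalize DAPI and segment nuclei; standardize GFP
#' against the dataset-wide maximum; detect seeds, screen mitoses, grow
#' counting and area masks; remove clustered and border nuclei; extract
#' per-cell records. Per-image failures are logged and skipped (reported
#' in the manifest). A run manifest (parameter echo, inputs, seeds, per-
#' stage outcomes, package version) is returned and, when \code{out_dir}
#' is given, written as JSON beside mask PNGs and a records CSV.
#'
#' @param triplets nonempty list of \linkS4class{ImageTriplet} objects.
#' @param params a \linkS4class{SegParams}.
#' @param out_dir optional output directory.
#' @return A list: \code{records} (combined data.frame with an \code{id}
#'   column), \code{summary} (from \code{\link{summarizeFeatures}}),
#'   \code{masks} (per-image list of nucleus/counting/area masks),
#'   \code{manifest}.
#' @export
runFluorescencePipeline <- function(triplets, params = segParams(),
                                    out_dir = NULL) {
  if (length(triplets) == 0) stop("empty input list")
  dataset_max <- max(vapply(triplets, function(t) max(gfp(t)), numeric(1)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("nucleoDHM")),
    n_inputs = length(triplets),
    dataset_max = dataset_max,
    params = {
      sn <- slotNames("SegParams")
      stats::setNames(lapply(sn, function(s) slot(params, s)), sn)
    },
    images = list())
  records <- NULL
  masks <- list()
  for (t in triplets) {
    id <- t@id
    res <- tryCatch({
      nmask <- segmentNuclei(dapi(t), params)
      gstd <- standardizeGfp(gfp(t), nmask, dataset_max, params)
      nl <- segmentNucleoli(gstd, nmask, params)
      filt <- removeClusteredAndBorder(nmask, nl, params)
      ps <- pixelSizeUm(optics(t))
      kept_seeds <- nl$seeds[nl$seeds$kept, , drop = FALSE]
      rec <- extractFeatures(filt$nucleus_mask,
                             filt$nucleolus_masks$counting,
                             filt$nucleolus_masks$area, ps,
                             seeds = kept_seeds)
      list(ok = TRUE, rec = rec, nmask = filt$nucleus_mask,
           counting = filt$nucleolus_masks$counting,
           area = filt$nucleolus_masks$area,
           removed = filt$removed, seeds = nl$seeds)
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    if (res$ok) {
      r <- res$rec
      if (nrow(r) > 0) r <- cbind(id = id, r)
      records <- rbind(records, r)
      masks[[id]] <- list(nucleus = res$nmask, counting = res$counting,
                          area = res$area)
      manifest$images[[id]] <- list(
        status = "ok", n_cells = nrow(res$rec),
        n_seeds = nrow(res$seeds),
        n_seeds_kept = sum(res$seeds$kept),
        n_removed_nuclei = nrow(res$removed))
    } else {
      manifest$images[[id]] <- list(status = "failed", error = res$error)
    }
  }
  n_failed <- sum(vapply(manifest$images,
                         function(x) x$status == "failed", logical(1)))
  manifest$n_failed <- n_failed
  summary <- if (!is.null(records) && nrow(records) > 0)
    summarizeFeatures(records) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(masks)) {
      writeMaskPng(masks[[id]]$nucleus,
                   file.path(out_dir, paste0(id, "_nucleus.png")))
      writeMaskPng(masks[[id]]$counting,
                   file.path(out_dir, paste0(id, "_counting.png")))
      writeMaskPng(masks[[id]]$area,
                   file.path(out_dir, paste0(id, "_area.png")))
    }
    if (!is.null(records))
      utils::write.csv(records[setdiff(names(records),
                                       "nucleolar_areas_um2")],
                       file.path(out_dir, "records.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(records = records, summary = summary, masks = masks,
       manifest = manifest)
}

#' Run the optical-thickness workflow over labelled conditions
#'
#' Computes the nucleolar optical-thickness index for every nucleolus of
#' every sample: the nucleolus center is the brightest phase pixel of its
#' area region; the background disc sits in the adjacent nucleoplasm (or
#' outside the nucleus in \code{"extranuclear"} mode). Per-condition
#' summaries report the mean index and, against the reference condition,
#' the percent change.
#'
#' @param samples nonempty list; each element a list with \code{phase}
#'   (matrix, radians), \code{nucleus_mask}, \code{area_mask} (aligned 0/1
#'   matrices) and \code{condition} (character).
#' @param params a \linkS4class{ThicknessParams}.
#' @param optics an \linkS4class{OpticsConfig}.
#' @param reference reference condition; defaults to the first seen.
#' @return A list: \code{indices} (data.frame: sample, condition,
#'   nucleolus, index_nm, opl_nucleolus, opl_background) and
#'   \code{summary} (data.frame: condition, n, mean_index_nm,
#'   pct_change).
#' @export
runThicknessPipeline <- function(samples, params = thicknessParams(),
                                 optics = opticsConfig(),
                                 reference = NULL) {
  if (length(samples) == 0) stop("empty input list")
  rows <- NULL
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    if (is.null(s$phase) || is.null(s$nucleus_mask) || is.null(s$area_mask))
      stop("each sample needs 'phase', 'nucleus_mask' and 'area_mask'")
    if (!identical(dim(s$phase), dim(s$nucleus_mask)))
      stop("phase and masks of sample ", si, " have different shapes; ",
           "upsample the phase image first (preprocessPhase)")
    alab <- cpp_label8(s$area_mask)
    for (l in seq_len(max(alab))) {
      reg <- (alab == l) + 0L
      idx <- which(reg == 1)
      vals <- s$phase[idx]
      best <- idx[which.max(vals)]
      ctr <- c((best - 1L) %% nrow(s$phase) + 1L,
               (best - 1L) %/% nrow(s$phase) + 1L)
      bg <- if (params@background_mode == "nucleoplasm")
        nucleoplasmBackgroundCenter(ctr, s$nucleus_mask, s$area_mask)
      else .extranuclearCenter(ctr, s$nucleus_mask)
      ti <- thicknessIndex(s$phase, ctr, bg, params, optics)
      rows <- rbind(rows, data.frame(
        sample = si, condition = s$condition, nucleolus = l,
        index_nm = ti$index, opl_nucleolus = ti$opl_nucleolus,
        opl_background = ti$opl_background))
    }
  }
  if (is.null(rows)) stop("no nucleoli found in any sample")
  conds <- unique(rows$condition)
  if (is.null(reference)) reference <- conds[1]
  means <- vapply(conds, function(cc)
    mean(rows$index_nm[rows$condition == cc]), numeric(1))
  ref_mean <- means[match(reference, conds)]
  summary <- data.frame(
    condition = conds,
    n = vapply(conds, function(cc) sum(rows$condition == cc), integer(1)),
    mean_index_nm = unname(means),
    pct_change = ifelse(conds == reference, NA_real_,
                        100 * (unname(means) - ref_mean) / ref_mean))
  if (length(conds) == 1) summary$pct_change <- NULL
  list(indices = rows, summary = summary)
}

.extranuclearCenter <- function(nucleolus_center, nucleus_mask,
                                clearance_px = 4) {
  excl <- .as01(EBImage::dilate(nucleus_mask, .brush(clearance_px)))
  cand <- which(excl == 0)
  if (length(cand) == 0) stop("no extranuclear pixel available")
  H <- nrow(nucleus_mask)
  r <- (cand - 1L) %% H + 1L
  c <- (cand - 1L) %/% H + 1L
  d2 <- (r - nucleolus_center[1])^2 + (c - nucleolus_center[2])^2
  o <- order(d2, r, c)[1]
  c(r[o], c[o])
}

#' Percent change between condition means
#'
#' Utility for dose-response style comparisons: given per-condition mean
#' indices, the percent change of each condition against the reference.
#'
#' @param means named numeric vector of condition means.
#' @param reference name of the reference condition.
#' @return Named numeric vector of percent changes (reference omitted).
#' @examples
#' percentChange(c(ctrl = 78.19, medium = 85.58, high = 103.2), "ctrl")
#' @export
percentChange <- function(means, reference = names(means)[1]) {
  stopifnot(!is.null(names(means)), reference %in% names(means))
  ref <- means[[reference]]
  out <- 100 * (means[names(means) != reference] - ref) / ref
  out
}
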