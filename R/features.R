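#' Extract per-cell nucleolar parameters
#'
#' For every connected nucleus region: the nucleolus count (number of
#' counting-mask regions assigned to it), the individual and total
#' nucleolar areas (area-mask regions, pixel counts times pixel size
#' squared) and the nucleolar-to-nuclear area ratio. A nucleolus region is
#' assigned to the nucleus containing its seed pixel; since both masks are
#' already restricted to the nucleus mask a region spanning two nuclei
#' cannot occur and is asserted against.
#'
#' @param nucleus_mask,counting_mask,area_mask aligned 0/1 matrices.
#' @param pixel_size_um pixel size in um/pixel (see
#'   \code{\link{pixelSizeUm}}).
#' @param seeds optional data.frame with columns row, col (the kept seeds);
#'   when supplied, counting regions are assigned through their seed pixel,
#'   otherwise through their constituent pixels.
#' @return A data.frame with one row per nucleus: \code{nucleus_label},
#'   \code{nucleus_area_um2}, \code{nucleolus_count},
#'   \code{total_nucleolar_area_um2}, \code{nucleolar_to_nuclear_ratio}
#'   and a list column \code{nucleolar_areas_um2}.
#' @export
extractFeatures <- function(nucleus_mask, counting_mask, area_mask,
                            pixel_size_um, seeds = NULL) {
  stopifnot(identical(dim(nucleus_mask), dim(counting_mask)),
            identical(dim(nucleus_mask), dim(area_mask)),
            pixel_size_um > 0)
  ps2 <- pixel_size_um^2
  nlab <- cpp_label8(nucleus_mask)
  n_nuc <- max(nlab)
  assign_region <- function(idx) {
    labs <- unique(nlab[idx])
    labs <- labs[labs > 0]
    if (length(labs) == 0) return(NA_integer_)
    if (length(labs) > 1)
      stop("nucleolus region spans two nuclei; masks were not restricted")
    labs
  }
  clab <- cpp_label8(counting_mask)
  counts <- integer(n_nuc)
  for (l in seq_len(max(clab))) {
    idx <- which(clab == l)
    owner <- if (!is.null(seeds)) {
      hit <- which(clab[cbind(seeds$row, seeds$col)] == l)
      if (length(hit) > 0) nlab[seeds$row[hit[1]], seeds$col[hit[1]]]
      else assign_region(idx)
    } else assign_region(idx)
    if (!is.na(owner) && owner > 0) counts[owner] <- counts[owner] + 1L
  }
  alab <- cpp_label8(area_mask)
  areas <- replicate(n_nuc, numeric(0), simplify = FALSE)
  for (l in seq_len(max(alab))) {
    idx <- which(alab == l)
    owner <- assign_region(idx)
    if (!is.na(owner) && owner > 0)
      areas[[owner]] <- c(areas[[owner]], length(idx) * ps2)
  }
  nuc_areas <- if (n_nuc > 0)
    tabulate(nlab[nlab > 0], nbins = n_nuc) * ps2 else numeric(0)
  total <- vapply(areas, sum, numeric(1))
  data.frame(
    nucleus_label = seq_len(n_nuc),
    nucleus_area_um2 = nuc_areas,
    nucleolus_count = counts,
    total_nucleolar_area_um2 = total,
    nucleolar_to_nuclear_ratio = ifelse(nuc_areas > 0, total / nuc_areas, 0),
    nucleolar_areas_um2 = I(areas)
  )
}

#' Summarize per-cell records
#'
#' Computes the clinical summary statistics: mean number of nucleoli per
#' cell, mean nucleolar area (by default averaged per nucleolus over all
#' individual nucleoli; set \code{area_average = "per_cell"} to average
#' per-cell totals instead), mean nucleolar-to-nuclear ratio, and the
#' histogram of cells with 1-8 nucleoli. Cells with zero detected nucleoli
#' remain in the count statistics but contribute nothing to the mean
#' nucleolar area (their per-nucleolus area is undefined); their number is
#' reported as \code{n_zero}.
#'
#' @param records data.frame from \code{\link{extractFeatures}} (rows from
#'   several images may be concatenated).
#' @param area_average \code{"per_nucleolus"} or \code{"per_cell"}.
#' @return A list: \code{mean_count}, \code{mean_nucleolar_area_um2},
#'   \code{mean_ratio}, \code{count_histogram} (named vector, classes
#'   1-8), \code{n_cells}, \code{n_nucleoli}, \code{n_zero}.
#' @export
summarizeFeatures <- function(records,
                              area_average = c("per_nucleolus", "per_cell")) {
  if (is.null(records) || nrow(records) == 0)
    stop("empty record list: nothing to summarize")
  area_average <- match.arg(area_average)
  all_areas <- unlist(records$nucleolar_areas_um2)
  with_nucleoli <- records$nucleolus_count > 0
  mean_area <- if (area_average == "per_nucleolus") {
    if (length(all_areas) > 0) mean(all_areas) else NA_real_
  } else {
    if (any(with_nucleoli))
      mean(records$total_nucleolar_area_um2[with_nucleoli]) else NA_real_
  }
  hist <- vapply(1:8, function(k) sum(records$nucleolus_count == k),
                 integer(1))
  names(hist) <- 1:8
  list(
    mean_count = mean(records$nucleolus_count),
    mean_nucleolar_area_um2 = mean_area,
    mean_ratio = mean(records$nucleolar_to_nuclear_ratio),
    count_histogram = hist,
    n_cells = nrow(records),
    n_nucleoli = sum(records$nucleolus_count),
    n_zero = sum(!with_nucleoli)
  )
}
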