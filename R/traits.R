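#' Callus- and shoot-area proportions from a segmentation mask
#'
#' The two image-derived traits: the fraction of total plant area (stem +
#' callus + shoot pixels; background excluded from the denominator)
#' labelled callus, and labelled shoot. A mask with no plant pixels yields
#' missing values rather than zeros, so empty images do not inflate the
#' zero class of these already zero-heavy traits.
#'
#' @param mask integer label matrix (see [simulate_masks()] /
#'   [read_mask_png()]).
#' @param class_map named integer vector mapping class names
#'   (`background`, `stem`, `callus`, `shoot`) to label values.
#' @return named numeric vector `c(callus_area =, shoot_area =)`; both `NA`
#'   when the mask has no plant pixel.
#' @export
mask_class_proportions <- function(mask,
                                   class_map = c(background = 0L, stem = 1L,
                                                 callus = 2L, shoot = 3L)) {
  lab <- as.integer(mask)
  if (any(!lab %in% class_map))
    stop("mask contains labels outside the class map", call. = FALSE)
  n_stem <- sum(lab == class_map[["stem"]])
  n_cal <- sum(lab == class_map[["callus"]])
  n_sho <- sum(lab == class_map[["shoot"]])
  n_plant <- n_stem + n_cal + n_sho
  if (n_plant == 0L)
    return(c(callus_area = NA_real_, shoot_area = NA_real_))
  c(callus_area = n_cal / n_plant, shoot_area = n_sho / n_plant)
}

#' Trait table from a set of masks
#'
#' @param masks list of segmentation masks.
#' @param meta data frame with one row per mask: `genotype_id`,
#'   `replicate`, `timepoint` and any covariate columns to carry through.
#' @inheritParams mask_class_proportions
#' @return trait table with `callus_area` / `shoot_area` columns appended.
#' @export
masks_to_traits <- function(masks, meta,
                            class_map = c(background = 0L, stem = 1L,
                                          callus = 2L, shoot = 3L)) {
  stopifnot(length(masks) == nrow(meta))
  props <- t(vapply(masks, mask_class_proportions, numeric(2),
                    class_map = class_map))
  cbind(as.data.frame(meta), as.data.frame(props))
}

#' Merge replicate plants into per-genotype trait values
#'
#' The arithmetic mean of the replicates is used where both are present;
#' a single non-missing replicate passes through unchanged; the merged
#' value is missing only when every replicate is missing. Idempotent on
#' already-merged tables (a single "replicate" per genotype x timepoint).
#'
#' @param traits trait table with columns `genotype_id`, `replicate`,
#'   `timepoint`, trait columns, and covariates (covariates must be
#'   constant within genotype).
#' @param trait_cols names of the trait columns to average.
#' @return trait table with one row per genotype x timepoint and no
#'   `replicate` column.
#' @export
merge_replicates <- function(traits,
                             trait_cols = intersect(c("callus_area", "shoot_area"),
                                                    names(traits))) {
  stopifnot(all(c("genotype_id", "timepoint") %in% names(traits)))
  key <- interaction(traits$genotype_id, traits$timepoint, drop = TRUE)
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  first_row <- !duplicated(key)
  out <- traits[first_row, setdiff(names(traits), c("replicate", trait_cols)),
                drop = FALSE]
  for (tc in trait_cols)
    out[[tc]] <- as.numeric(tapply(traits[[tc]], key, mean_or_na))[
      match(key[first_row], levels(key))]
  rownames(out) <- NULL
  out[order(out$genotype_id, out$timepoint), , drop = FALSE]
}
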