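#' Simulate segmentation masks with known class proportions
#'
#' Builds one single-channel label mask per trait row: a contiguous
#' disc-shaped "plant" region centred in the image, whose pixels are
#' assigned to callus, shoot and unregenerated stem so that the class
#' proportions (out of plant pixels, background excluded) match the
#' requested `callus_area` / `shoot_area` to within one pixel. Pixel labels
#' follow the convention `0` background, `1` stem, `2` callus, `3` shoot.
#'
#' @param trait_rows data frame with columns `callus_area` and `shoot_area`
#'   (each in `[0, 1]`, summing to at most 1 per row).
#' @param image_size side length of the square mask in pixels.
#' @param seed integer seed controlling the (slight) jitter of the plant
#'   region size.
#' @return a list of integer matrices of class `segmentation_mask`, one per
#'   row of `trait_rows`.
#' @export
simulate_masks <- function(trait_rows, image_size = 64L, seed = 1L) {
  trait_rows <- as.data.frame(trait_rows)
  stopifnot(all(c("callus_area", "shoot_area") %in% names(trait_rows)))
  p <- trait_rows[, c("callus_area", "shoot_area")]
  if (any(p < 0) || any(p > 1) || any(rowSums(p) > 1 + 1e-12))
    stop("requested proportions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  set.seed(seed)
  lapply(seq_len(nrow(trait_rows)), function(i) {
    r <- image_size * runif(1, 0.25, 0.4)
    ctr <- (image_size + 1) / 2
    d2 <- outer(seq_len(image_size), seq_len(image_size),
                function(x, y) (x - ctr)^2 + (y - ctr)^2)
    plant <- which(d2 <= r^2)
    # order plant pixels by angle so class sectors stay spatially coherent
    ang <- atan2((plant - 1) %/% image_size + 1 - ctr,
                 (plant - 1) %% image_size + 1 - ctr)
    plant <- plant[order(ang)]
    n_plant <- length(plant)
    n_cal <- round(trait_rows$callus_area[i] * n_plant)
    n_sho <- round(trait_rows$shoot_area[i] * n_plant)
    if (n_cal + n_sho > n_plant) n_sho <- n_plant - n_cal
    lab <- matrix(0L, image_size, image_size)
    lab[plant] <- 1L
    if (n_cal > 0) lab[plant[seq_len(n_cal)]] <- 2L
    if (n_sho > 0) lab[plant[n_cal + seq_len(n_sho)]] <- 3L
    structure(lab, class = c("segmentation_mask", "matrix", "array"))
  })
}
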