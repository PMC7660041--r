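#' Standard 10-10 montages and sensorimotor electrode pools
#'
#' `montage_64()` returns the 64 channel labels of the extended 10-10 cap
#' used for recording; `montage_compact()` a 16-channel subset that contains
#' every pooled sensorimotor electrode (useful for fast simulation studies).
#'
#' @return Character vector of channel labels.
#' @export
montage_64 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2", "M1", "M2")
}

#' @rdname montage_64
#' @export
montage_compact <- function() {
  c("F3", "F4", "Fz", "Cz", "C1", "C2", "C3", "C4",
    "CP1", "CP2", "CP3", "CP4", "CPz", "P3", "P4", "Pz")
}

# Source-to-channel weights for the left and right sensorimotor beta sources.
# Peaked over the hand-knob region; channels absent from the montage in use
# are simply dropped.
source_topography <- function(hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  left <- c(C3 = 1.0, CP3 = 0.85, C1 = 0.8, CP1 = 0.7,
            C5 = 0.5, CP5 = 0.45, FC3 = 0.4, FC1 = 0.35, P3 = 0.3)
  if (hemisphere == "left") return(left)
  names(left) <- c("C4", "CP4", "C2", "CP2", "C6", "CP6", "FC4", "FC2", "P4")
  left
}

#' Sensorimotor electrode pools for beta measures
#'
#' The electrode pools over sensorimotor cortex used to extract
#' movement-related beta desynchronization (MRBD), post-movement beta
#' rebound (PMBR) and pre-movement (resting) beta power, per hemisphere.
#' The resting pool is the union of the MRBD and PMBR pools within each
#' hemisphere.
#'
#' @param mrbd_left,mrbd_right,pmbr_left,pmbr_right Channel label vectors;
#'   defaults are the standard pools ('C3' 'CP3' 'CP1' / 'C4' 'CP4' 'CP2'
#'   for MRBD and 'C1' 'C3' 'CP3' / 'C2' 'C4' 'CP4' for PMBR).
#' @param rest_left,rest_right Optional overrides for the resting pools.
#' @return An object of class `electrode_pools`: a named list with
#'   `mrbd`, `pmbr`, `rest`, each holding `left`/`right` label vectors.
#' @export
electrode_pools <- function(mrbd_left = c("C3", "CP3", "CP1"),
                            mrbd_right = c("C4", "CP4", "CP2"),
                            pmbr_left = c("C1", "C3", "CP3"),
                            pmbr_right = c("C2", "C4", "CP4"),
                            rest_left = NULL,
                            rest_right = NULL) {
  pools <- list(
    mrbd = list(left = mrbd_left, right = mrbd_right),
    pmbr = list(left = pmbr_left, right = pmbr_right),
    rest = list(left = if (is.null(rest_left)) union(mrbd_left, pmbr_left) else rest_left,
                right = if (is.null(rest_right)) union(mrbd_right, pmbr_right) else rest_right)
  )
  structure(pools, class = "electrode_pools")
}

# All channels any pool references.
pool_channels <- function(pools) {
  unique(unlist(pools, use.names = FALSE))
}

# Map pool hemispheres to contralateral/ipsilateral given the trained hand.
# Training the right hand puts the contralateral sensorimotor cortex on the
# left; the generator's mirror flag is simply the trained hand label.
hemisphere_map <- function(trained_hand = c("right", "left")) {
  trained_hand <- match.arg(trained_hand)
  if (trained_hand == "right") {
    c(contralateral = "left", ipsilateral = "right")
  } else {
    c(contralateral = "right", ipsilateral = "left")
  }
}
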