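#' Tissue signature for a planted lesion subregion
#'
#' A habitat signature describes one tissue class by its mean intensity on
#' each channel and a common within-habitat noise level. T1 and T2 means are
#' in arbitrary scanner units; ADC is on the clinical scale in units of
#' 10^-3 mm^2/s (so `1.0` means 1.0e-3 mm^2/s).
#'
#' @param name Label for the tissue class.
#' @param mean_t1,mean_t2,mean_adc Channel intensity means.
#' @param sd Within-habitat Gaussian noise standard deviation (> 0), applied
#'   independently per voxel and channel.
#' @return A `habitat_signature` object (named list).
#' @examples
#' habitat_signature("triad", 2.6, 2.4, 0.9, sd = 0.15)
#' @export
habitat_signature <- function(name, mean_t1, mean_t2, mean_adc, sd = 0.15) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(sd) || length(sd) != 1 || sd <= 0) {
    stop("signature 'sd' must be a single positive number")
  }
  structure(
    list(name = name, mean_t1 = mean_t1, mean_t2 = mean_t2,
         mean_adc = mean_adc, sd = sd),
    class = "habitat_signature"
  )
}

signature_means <- function(sig) {
  c(t1 = sig$mean_t1, t2 = sig$mean_t2, adc = sig$mean_adc)
}

#' Default three-signature configuration
#'
#' Three well-separated tissue classes mirroring the habitats seen in uterine
#' lesions: a cystic/degenerative class (low T1, high T2, high ADC), a viable
#' stromal class (intermediate signal) and the "malignant triad" class
#' (high T1 from subacute hemorrhage, high T2 from edema/necrosis, low ADC
#' from hypercellularity). The triad ADC mean sits below the 1.29 (x 10^-3
#' mm^2/s) clinical decision threshold. Pairwise Euclidean separation of
#' channel means is at least 4 times the noise SD.
#'
#' @param sd Shared within-habitat noise SD.
#' @return List of three `habitat_signature` objects.
#' @export
default_signatures <- function(sd = 0.15) {
  sigs <- list(
    habitat_signature("cystic", mean_t1 = 1.0, mean_t2 = 2.6, mean_adc = 1.50, sd = sd),
    habitat_signature("stroma", mean_t1 = 1.8, mean_t2 = 1.4, mean_adc = 1.20, sd = sd),
    habitat_signature("triad",  mean_t1 = 2.6, mean_t2 = 2.4, mean_adc = 0.90, sd = sd)
  )
  check_signature_separation(sigs)
  sigs
}

check_signature_separation <- function(signatures, factor = 4) {
  if (length(signatures) < 2) return(invisible(TRUE))
  means <- t(vapply(signatures, signature_means, numeric(3)))
  sds <- vapply(signatures, function(s) s$sd, numeric(1))
  for (i in seq_len(nrow(means) - 1)) {
    for (j in (i + 1):nrow(means)) {
      d <- sqrt(sum((means[i, ] - means[j, ])^2))
      if (d < factor * max(sds[i], sds[j])) {
        warning(sprintf(
          "signatures '%s' and '%s' separated by %.3f < %g * sd; habitats may not be recoverable",
          signatures[[i]]$name, signatures[[j]]$name, d, factor
        ))
      }
    }
  }
  invisible(TRUE)
}
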