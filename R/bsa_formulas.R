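#' The anthropometric BSA models
#'
#' @return Character vector of supported model names.
#' @export
bsaModels <- function() c("dubois", "mosteller", "haycock", "boyd", "gehan_george")

.check_subject <- function(height_m, weight_kg) {
  if (any(!is.finite(height_m)) || any(!is.finite(weight_kg)) ||
      any(height_m < 0.3) || any(height_m > 2.6) ||
      any(weight_kg < 1) || any(weight_kg > 400))
    stop("implausible anthropometrics", call. = FALSE)
}

#' Formula-based body surface area
#'
#' The five classical height/weight BSA models. The public interface is always
#' metres and kilograms; each formula converts internally to its native units
#' (Du Bois as published here takes H in metres, the others take centimetres,
#' Boyd takes weight in grams):
#' \itemize{
#'   \item Du Bois & Du Bois: `0.20247 * H_m^0.725 * W_kg^0.425`
#'   \item Mosteller: `sqrt(H_cm * W_kg / 3600)`
#'   \item Haycock: `0.024265 * H_cm^0.3964 * W_kg^0.5378`
#'   \item Boyd: `0.0003207 * H_cm^0.3 * W_g^(0.7285 - 0.0188 * log10(W_g))`
#'   \item Gehan & George: `0.0235 * H_cm^0.42246 * W_kg^0.51456`
#' }
#'
#' @param model one of [bsaModels()].
#' @param height_m stature in metres (0.3--2.6).
#' @param weight_kg body mass in kilograms (1--400).
#' @return BSA in m^2 (vectorised over subjects).
#' @export
bsaFormula <- function(model, height_m, weight_kg) {
  if (length(model) != 1L || !model %in% bsaModels())
    stop("unknown model", call. = FALSE)
  .check_subject(height_m, weight_kg)
  h_cm <- height_m * 100
  switch(model,
    dubois = 0.20247 * height_m^0.725 * weight_kg^0.425,
    mosteller = sqrt(h_cm * weight_kg / 3600),
    haycock = 0.024265 * h_cm^0.3964 * weight_kg^0.5378,
    boyd = {
      w_g <- weight_kg * 1000
      0.0003207 * h_cm^0.3 * w_g^(0.7285 - 0.0188 * log10(w_g))
    },
    gehan_george = 0.0235 * h_cm^0.42246 * weight_kg^0.51456)
}

#' First-order BSA error propagation (Du Bois)
#'
#' Relative change of the Du Bois BSA for small height/weight changes:
#' `dBSA/BSA = 0.725 * dH/H + 0.425 * dW/W`, returned as a signed percentage.
#'
#' @param height_m,weight_kg baseline anthropometrics (m, kg).
#' @param d_height_m,d_weight_kg perturbations (m, kg).
#' @return Signed percent relative BSA change.
#' @export
bsaRelativeError <- function(height_m, weight_kg, d_height_m = 0,
                             d_weight_kg = 0) {
  .check_subject(height_m, weight_kg)
  if (any(height_m == 0) || any(weight_kg == 0))
    stop("division by zero", call. = FALSE)
  100 * (0.725 * d_height_m / height_m + 0.425 * d_weight_kg / weight_kg)
}

#' Evaluate all BSA models for a subject table
#'
#' @param subjects data.frame with columns `id`, `height_m`, `weight_kg` (as
#'   read from a subject CSV).
#' @return The input with one added column per model (`bsa_<model>_m2`).
#' @export
bsaTable <- function(subjects) {
  stopifnot(all(c("id", "height_m", "weight_kg") %in% names(subjects)))
  for (m in bsaModels())
    subjects[[paste0("bsa_", m, "_m2")]] <-
      bsaFormula(m, subjects$height_m, subjects$weight_kg)
  subjects
}
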