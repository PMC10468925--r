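# Published group-level layer profiles for a 42-patient small-vessel-disease
# cohort: per lesion class (PV = periventricular, DEEP = deep), across-subject
# mean and SD of each imaging parameter over the WMH, the 15 concentric NAWM
# layers, and whole-brain NAWM. These numbers parameterize the synthetic
# cohort generator and the phantom calibration; they are not measurements made
# by this package. Units: CBF ml/100g/min; AD/MD/RD 1e-4 mm^2/s; FA/MK/AK/RK
# dimensionless.

PARAMETERS <- c("CBF", "AD", "AK", "FA", "MD", "MK", "RD", "RK")
REGIONS <- c("WMH", paste0("L", 1:15), "NAWM")
CLASSES <- c("PV", "DEEP")

# columns: CBF, AD, AK, FA, MD, MK, RD, RK; rows: WMH, L1..L15, NAWM
.deep_mean <- matrix(c(
  14.212, 15.130, 0.724, 0.285, 11.677, 0.846, 9.951, 0.976,
  14.492, 14.175, 0.769, 0.323, 10.529, 0.913, 8.706, 1.074,
  15.125, 13.8547, 0.796, 0.337, 10.157, 0.942, 8.312, 1.113,
  15.626, 13.636, 0.815, 0.348, 9.894, 0.964, 8.023, 1.146,
  16.066, 13.492, 0.829, 0.357, 9.705, 0.979, 7.812, 1.169,
  16.439, 13.430, 0.835, 0.363, 9.605, 0.987, 7.693, 1.183,
  16.799, 13.410, 0.838, 0.367, 9.553, 0.991, 7.624, 1.190,
  17.166, 13.399, 0.839, 0.370, 9.517, 0.991, 7.575, 1.194,
  17.489, 13.408, 0.839, 0.372, 9.500, 0.990, 7.545, 1.194,
  17.833, 13.413, 0.838, 0.373, 9.489, 0.988, 7.527, 1.192,
  18.197, 13.426, 0.837, 0.374, 9.493, 0.985, 7.527, 1.190,
  18.542, 13.446, 0.836, 0.374, 9.506, 0.982, 7.536, 1.187,
  19.145, 13.471, 0.834, 0.373, 9.527, 0.978, 7.555, 1.184,
  19.719, 13.492, 0.832, 0.372, 9.549, 0.974, 7.577, 1.179,
  19.762, 13.523, 0.831, 0.372, 9.574, 0.970, 7.600, 1.175,
  19.943, 13.562, 0.829, 0.371, 9.611, 0.964, 7.636, 1.168,
  20.037, 13.353, 0.835, 0.344, 9.737, 0.910, 7.929, 1.047),
  nrow = 17, byrow = TRUE, dimnames = list(REGIONS, PARAMETERS))

.deep_sd <- matrix(c(
  5.708, 1.472, 0.079, 0.041, 1.229, 0.078, 1.192, 0.119,
  5.219, 1.200, 0.063, 0.035, 0.891, 0.065, 0.820, 0.131,
  4.893, 1.081, 0.061, 0.032, 0.789, 0.069, 0.718, 0.146,
  4.731, 1.039, 0.063, 0.031, 0.771, 0.075, 0.707, 0.161,
  4.595, 1.008, 0.066, 0.029, 0.734, 0.079, 0.661, 0.173,
  4.482, 0.999, 0.065, 0.028, 0.723, 0.082, 0.645, 0.180,
  4.361, 0.997, 0.062, 0.028, 0.713, 0.085, 0.631, 0.185,
  4.254, 0.971, 0.059, 0.028, 0.686, 0.086, 0.607, 0.187,
  4.182, 0.950, 0.058, 0.028, 0.658, 0.087, 0.581, 0.188,
  4.131, 0.926, 0.056, 0.029, 0.635, 0.086, 0.565, 0.188,
  4.100, 0.925, 0.055, 0.030, 0.643, 0.086, 0.582, 0.199,
  4.116, 0.937, 0.053, 0.030, 0.654, 0.087, 0.595, 0.199,
  4.174, 0.948, 0.052, 0.031, 0.677, 0.088, 0.623, 0.199,
  4.167, 0.946, 0.051, 0.031, 0.690, 0.087, 0.643, 0.187,
  4.293, 0.972, 0.049, 0.032, 0.706, 0.087, 0.658, 0.185,
  4.388, 1.018, 0.049, 0.033, 0.752, 0.086, 0.701, 0.183,
  4.343, 0.437, 0.040, 0.021, 0.403, 0.075, 0.421, 0.148),
  nrow = 17, byrow = TRUE, dimnames = list(REGIONS, PARAMETERS))

.pv_mean <- matrix(c(
  11.399, 19.356, 0.619, 0.221, 15.900, 0.681, 14.172, 0.751,
  11.406, 16.673, 0.697, 0.309, 12.648, 0.815, 10.635, 0.954,
  11.840, 16.080, 0.731, 0.346, 11.804, 0.871, 9.667, 1.044,
  12.306, 15.698, 0.758, 0.376, 11.201, 0.916, 8.953, 1.118,
  12.891, 15.404, 0.777, 0.393, 10.776, 0.946, 8.462, 1.169,
  13.531, 15.138, 0.792, 0.403, 10.451, 0.966, 8.107, 1.204,
  14.263, 14.888, 0.805, 0.408, 10.191, 0.980, 7.843, 1.227,
  15.009, 14.663, 0.817, 0.411, 9.992, 0.989, 7.657, 1.241,
  15.760, 14.477, 0.827, 0.411, 9.852, 0.993, 7.539, 1.245,
  16.509, 14.319, 0.834, 0.410, 9.750, 0.995, 7.465, 1.243,
  17.209, 14.191, 0.838, 0.408, 9.679, 0.995, 7.423, 1.239,
  17.875, 14.066, 0.841, 0.405, 9.621, 0.993, 7.398, 1.231,
  18.481, 13.949, 0.843, 0.402, 9.562, 0.990, 7.390, 1.221,
  19.050, 13.799, 0.845, 0.398, 9.548, 0.987, 7.382, 1.211,
  19.753, 13.765, 0.846, 0.394, 9.485, 0.982, 7.377, 1.198,
  20.079, 13.605, 0.847, 0.389, 9.450, 0.978, 7.383, 1.185,
  20.037, 13.353, 0.835, 0.344, 9.737, 0.910, 7.929, 1.047),
  nrow = 17, byrow = TRUE, dimnames = list(REGIONS, PARAMETERS))

.pv_sd <- matrix(c(
  3.784, 1.593, 0.057, 0.031, 1.371, 0.052, 1.336, 0.084,
  3.414, 0.906, 0.048, 0.038, 0.700, 0.064, 0.768, 0.131,
  3.246, 0.690, 0.045, 0.036, 0.620, 0.069, 0.728, 0.146,
  3.239, 0.586, 0.046, 0.031, 0.553, 0.070, 0.645, 0.157,
  3.299, 0.555, 0.048, 0.028, 0.506, 0.068, 0.574, 0.161,
  3.381, 0.569, 0.049, 0.028, 0.482, 0.068, 0.530, 0.164,
  3.502, 0.573, 0.049, 0.029, 0.475, 0.070, 0.524, 0.169,
  3.634, 0.574, 0.048, 0.031, 0.474, 0.071, 0.527, 0.174,
  3.788, 0.565, 0.046, 0.032, 0.459, 0.072, 0.521, 0.177,
  3.955, 0.545, 0.046, 0.033, 0.438, 0.072, 0.508, 0.178,
  4.128, 0.519, 0.046, 0.034, 0.406, 0.072, 0.485, 0.180,
  4.302, 0.507, 0.046, 0.034, 0.392, 0.073, 0.477, 0.182,
  4.449, 0.513, 0.046, 0.035, 0.384, 0.075, 0.477, 0.184,
  4.613, 0.539, 0.046, 0.035, 0.382, 0.076, 0.474, 0.183,
  4.708, 0.523, 0.046, 0.036, 0.393, 0.077, 0.478, 0.180,
  4.771, 0.551, 0.045, 0.037, 0.403, 0.078, 0.483, 0.178,
  4.343, 0.437, 0.040, 0.021, 0.403, 0.075, 0.421, 0.148),
  nrow = 17, byrow = TRUE, dimnames = list(REGIONS, PARAMETERS))

#' Reference cohort layer profile
#'
#' Published mean and between-subject SD of each imaging parameter over the
#' WMH, layers L1-L15 and whole-brain NAWM, per lesion class, from a 42-patient
#' cerebral small vessel disease cohort. These values are the calibration
#' defaults of the synthetic generators.
#'
#' @param class_label `"PV"` (periventricular) or `"DEEP"`.
#' @return data frame with columns `region`, `parameter`, `mean`, `sd`;
#'   regions ordered WMH, L1..L15, NAWM.
#' @export
reference_profile <- function(class_label = c("DEEP", "PV")) {
  class_label <- match.arg(class_label)
  m <- if (class_label == "DEEP") .deep_mean else .pv_mean
  s <- if (class_label == "DEEP") .deep_sd else .pv_sd
  data.frame(
    region = factor(rep(REGIONS, times = length(PARAMETERS)), levels = REGIONS),
    parameter = rep(PARAMETERS, each = length(REGIONS)),
    mean = as.vector(m),
    sd = as.vector(s),
    stringsAsFactors = FALSE
  )
}

#' Reported penumbra extents
#'
#' The published penumbra extents (mm) per lesion class and parameter: the
#' CBF extent from the layer-versus-whole-brain-NAWM rule, the structural
#' extents from the adjacent-layer rule. Used as the default ground-truth
#' transition distances of the phantom generator.
#'
#' @return data frame with columns `class`, `parameter`, `extent_mm`.
#' @export
reference_extents <- function() {
  data.frame(
    class = rep(c("DEEP", "PV"), each = 8L),
    parameter = rep(c("AD", "AK", "FA", "MD", "MK", "RD", "RK", "CBF"), 2L),
    extent_mm = c(5, 6, 8, 7, 6, 8, 6, 13,
                  13, 14, 7, 12, 9, 11, 8, 14),
    stringsAsFactors = FALSE
  )
}

reference_cell <- function(class_label, region, parameter, what = c("mean", "sd")) {
  what <- match.arg(what)
  m <- if (class_label == "DEEP") {
    if (what == "mean") .deep_mean else .deep_sd
  } else {
    if (what == "mean") .pv_mean else .pv_sd
  }
  m[region, parameter]
}
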