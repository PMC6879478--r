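# Published significant-feature tables of the two reference microRNA
# card studies, embedded verbatim as regression fixtures: a metastatic
# tumor panel (calibrator OLIGO, target POLY; 16 samples) and a non-small
# cell lung cancer panel (calibrator LA, target SCLC; 44 samples). Both
# were produced by an unpaired t-test on delta-Ct normalized data; rows
# are ordered by raw p-value and restricted to FC > 2 or FC < 0.5.

printed_de_columns <- c("genes", "t.test", "p.value", "adj.p.value", "ddCt",
                        "FC", "meanCalibrator", "meanTarget",
                        "categoryCalibrator", "categoryTarget")

printed_de_row <- function(gene, t, p, adj, ddct, fc, mc, mt, cc, ct_) {
  data.frame(genes = gene, t.test = t, p.value = p, adj.p.value = adj,
             ddCt = ddct, FC = fc, meanCalibrator = mc, meanTarget = mt,
             categoryCalibrator = cc, categoryTarget = ct_,
             stringsAsFactors = FALSE)
}

printed_metastatic <- function() {
  r <- printed_de_row
  rbind(
    r("hsa-miR-200c-4395411",    3.110, 0.011, 0.449, -4.414, 21.324, 25.793, 21.378, "OK", "OK"),
    r("hsa-miR-375-4373027",     2.558, 0.026, 0.560, -3.943, 15.381, 27.514, 23.570, "OK", "OK"),
    r("hsa-miR-141-4373137",     2.288, 0.043, 0.563, -3.640, 12.467, 28.392, 24.751, "OK", "OK"),
    r("hsa-miR-654-3p-4395350",  2.810, 0.019, 0.488, -3.008,  8.045, 34.747, 31.739, "Undetermined", "Undetermined"),
    r("hsa-miR-135b-4395372",    2.937, 0.013, 0.449, -2.916,  7.546, 28.848, 25.932, "OK", "OK"),
    r("hsa-miR-200b-4395362",    2.912, 0.014, 0.449, -2.516,  5.722, 24.808, 22.291, "OK", "OK"),
    r("hsa-miR-410-4378093",     2.299, 0.047, 0.563, -2.285,  4.873, 31.701, 29.417, "OK", "OK"),
    r("hsa-miR-323-3p-4395338",  2.209, 0.049, 0.563, -1.988,  3.966, 30.228, 28.240, "OK", "OK"),
    r("hsa-miR-370-4395386",     2.604, 0.021, 0.488, -1.686,  3.218, 27.286, 25.600, "OK", "OK"),
    r("hsa-miR-642-4380995",     2.807, 0.015, 0.449, -1.673,  3.188, 31.283, 29.610, "OK", "OK"),
    r("hsa-miR-127-3p-4373147",  2.338, 0.035, 0.563, -1.512,  2.853, 26.167, 24.655, "OK", "OK"),
    r("hsa-miR-212-4373087",     4.008, 0.001, 0.449, -1.422,  2.680, 27.481, 26.059, "OK", "OK"),
    r("hsa-miR-628-5p-4395544", -2.530, 0.032, 0.563,  1.097,  0.467, 29.281, 30.378, "OK", "Undetermined"),
    r("hsa-miR-125a-3p-4395310",-2.790, 0.017, 0.474,  1.191,  0.438, 29.835, 31.026, "OK", "OK"),
    r("hsa-miR-328-4373049",    -2.592, 0.028, 0.563,  1.215,  0.431, 27.772, 28.987, "OK", "OK"),
    r("hsa-miR-886-3p-4395305", -2.311, 0.042, 0.563,  1.225,  0.428, 24.007, 25.232, "OK", "OK"),
    r("hsa-miR-140-5p-4373374", -2.880, 0.012, 0.449,  1.245,  0.422, 23.457, 24.702, "OK", "OK"),
    r("hsa-miR-29c-4395171",    -2.926, 0.015, 0.449,  1.339,  0.395, 23.351, 24.691, "OK", "OK"),
    r("hsa-miR-140-3p-4395345", -3.118, 0.008, 0.449,  1.410,  0.376, 26.526, 27.935, "OK", "OK"),
    r("hsa-miR-570-4395458",    -2.305, 0.038, 0.563,  1.460,  0.363, 34.499, 35.959, "Undetermined", "Undetermined"),
    r("hsa-miR-489-4395469",    -3.029, 0.009, 0.449,  1.522,  0.348, 26.810, 28.332, "OK", "OK"),
    r("hsa-miR-545-4395378",    -3.097, 0.008, 0.449,  2.067,  0.239, 31.847, 33.914, "Undetermined", "Undetermined"),
    r("hsa-miR-502-5p-4373227", -3.107, 0.009, 0.449,  3.300,  0.102, 29.814, 33.113, "Undetermined", "Undetermined"))
}

printed_nslc <- function() {
  r <- printed_de_row
  rbind(
    r("hsa-miR-205-4373093",     5.190, 0.000, 0.001, -4.411, 21.272,  8.013, 3.602, "Undetermined", "Undetermined"),
    r("hsa-miR-375-4373027",    -4.079, 0.000, 0.038,  2.065,  0.239,  3.354, 5.418, "OK", "OK"),
    r("hsa-miR-422a-4395408",    3.854, 0.000, 0.069, -1.418,  2.673,  8.215, 6.796, "OK", "OK"),
    r("hsa-miR-149-4395366",     3.758, 0.001, 0.094, -2.322,  5.000,  7.393, 5.071, "OK", "Undetermined"),
    r("hsa-miR-708-4395452",     3.634, 0.001, 0.135, -2.044,  4.123,  5.995, 3.952, "OK", "OK"),
    r("hsa-miR-204-4373094",     3.440, 0.001, 0.232, -1.587,  3.004,  9.177, 7.590, "Undetermined", "Undetermined"),
    r("hsa-miR-483-5p-4395449",  3.376, 0.002, 0.285, -1.397,  2.634, 10.019, 8.622, "Undetermined", "Undetermined"),
    r("hsa-miR-127-3p-4373147",  2.984, 0.005, 0.918, -1.166,  2.245,  6.256, 5.090, "OK", "OK"),
    r("hsa-miR-196b-4395326",    2.915, 0.006, 1.000, -1.933,  3.818,  9.416, 7.483, "Undetermined", "Undetermined"),
    r("hsa-miR-202-4395474",     2.922, 0.006, 1.000, -1.061,  2.087, 10.305, 9.244, "Undetermined", "Undetermined"),
    r("hsa-miR-494-4395476",     2.669, 0.011, 1.000, -1.165,  2.242,  3.657, 2.492, "OK", "OK"),
    r("hsa-miR-376a-4373026",    2.628, 0.012, 1.000, -1.093,  2.133, 10.615, 9.522, "Undetermined", "Undetermined"),
    r("hsa-miR-376c-4395233",    2.624, 0.013, 1.000, -1.299,  2.460,  9.324, 8.025, "OK", "Undetermined"),
    r("hsa-miR-130b-4373144",    2.575, 0.014, 1.000, -1.071,  2.100,  8.247, 7.176, "Undetermined", "Undetermined"),
    r("hsa-miR-203-4373095",     2.131, 0.039, 1.000, -1.098,  2.140,  4.716, 3.618, "Undetermined", "OK"),
    r("hsa-miR-194-4373106",    -2.089, 0.046, 1.000,  1.182,  0.441,  8.508, 9.690, "OK", "Undetermined"))
}

#' Published significant-feature tables
#'
#' Returns one of the two published differential expression tables
#' embedded in the package as regression fixtures: `"metastatic"` (23
#' significant microRNAs; calibrator OLIGO, target POLY) or `"nslc"` (16
#' significant microRNAs; calibrator LA, target SCLC). Columns are the
#' standard differential expression output columns; values are verbatim
#' transcriptions of the published tables.
#'
#' @param study `"metastatic"` or `"nslc"`.
#' @return A data.frame with the standard DE columns.
#' @export
load_printed_de_table <- function(study = c("metastatic", "nslc")) {
  study <- match.arg(study)
  tab <- switch(study, metastatic = printed_metastatic(), nslc = printed_nslc())
  stopifnot(identical(names(tab), printed_de_columns))
  attr(tab, "study") <- study
  tab
}
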