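#' Sampling design of the Hainan Island study
#'
#' The nine sampling localities with their geographic group (NE/SW),
#' coordinates, recording air temperature and number of recorded males.
#' These printed values are the default sampling design for the synthetic
#' generator and the in-package arithmetic checks.
#'
#' @return Data.frame: `group`, `locality`, `longitude`, `latitude`,
#'   `temperature_c`, `n_males`.
#' @export
study_localities <- function() {
  data.frame(
    group = c(rep("NE", 6), rep("SW", 3)),
    locality = c("Haikou", "Huiwen", "Chengmai", "Lingao", "Danzhou",
                 "Yingjin", "Wuzhishan", "Lingshui", "Sanya"),
    longitude = c(110.25163, 110.73444, 110.00269, 109.72374, 109.56134,
                  109.28362, 109.59653, 110.01676, 109.48570),
    latitude = c(19.98020, 19.47056, 19.70805, 19.89148, 19.46854,
                 19.71347, 18.72689, 18.52668, 18.29662),
    temperature_c = c(27.9, 25.8, 27.0, 26.4, 27.0, 28.9, 26.7, 28.7, 29.0),
    n_males = c(3L, 2L, 4L, 3L, 4L, 5L, 4L, 6L, 2L)
  )
}

#' Published per-parameter call statistics of the study
#'
#' Grand means, SDs and the multi-level CV summaries of the six call
#' parameters, as reported for the full 33-male sample. These drive the
#' synthetic generator's defaults and the classification arithmetic
#' checks; they are inputs, not outputs, of this package.
#'
#' @return Data.frame keyed by `parameter`, with `mean`, `sd`,
#'   `cv_i_mean`, `cv_p_mean`, `cv_g_mean`, `cv_o`, and the published
#'   NE/SW group means `mean_ne` / `mean_sw`.
#' @export
study_call_statistics <- function() {
  data.frame(
    parameter = c("call_duration_ms", "call_interval_ms",
                  "dominant_frequency_hz", "bandwidth_hz",
                  "pulse_number", "pulse_rate_pps"),
    mean = c(215.1, 272.7, 3416, 2059, 14.0, 64.1),
    sd = c(37.6, 54.3, 522, 494, 1.6, 11.5),
    cv_i_mean = c(3.9, 10.4, 0.8, 2.8, 4.1, 2.0),
    cv_p_mean = c(8.3, 14.7, 4.3, 20.6, 8.3, 6.0),
    cv_g_mean = c(12.6, 21.5, 8.9, 20.2, 11.8, 12.4),
    cv_o = c(17.7, 22.5, 15.1, 23.9, 12.1, 17.9),
    mean_ne = c(224.3, 260.4, 3190, 1908, 13.9, 60.9),
    mean_sw = c(201.0, 296.3, 3783, 2307, 14.3, 69.1)
  )
}
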