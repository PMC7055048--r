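#' Health states of the physical-activity Markov model
#'
#' The model distinguishes nine mutually exclusive health states: three
#' physical-activity levels (inactive, < 200 MET-min/week; moderately
#' active, 200--450 MET-min/week; recommended activity, > 450 MET-min/week),
#' five chronic conditions associated with a lack of physical activity
#' (colorectal cancer, coronary heart disease, type 2 diabetes, stroke,
#' depression), and death. Death is the only absorbing state; the disease
#' states can only be left through death.
#'
#' @return A data.frame with columns `state` and `category`
#'   (`"activity"`, `"disease"` or `"absorbing"`), one row per state, in
#'   canonical state order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  data.frame(
    state = .states,
    category = c(rep("activity", 3), rep("disease", 5), "absorbing"),
    stringsAsFactors = FALSE
  )
}

# canonical state order used by every matrix and trace in the package
.states <- c(
  "inactive", "moderate", "recommended",
  "colorectal_cancer", "chd", "t2d", "stroke", "depression",
  "dead"
)

.activity_states <- .states[1:3]
.disease_states <- .states[4:8]

.arms <- c("eurofit", "control")
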