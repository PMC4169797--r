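#' Reported group means of the porcine ischemia-reperfusion experiment
#'
#' Published group-mean hemodynamics (10 animals) before and after a
#' 40-minute LAD occlusion with reperfusion: the experiment the phantom and
#' the segment-level generator emulate. These printed means serve as inputs
#' for worked-example derivations (stroke volume from EDV/ESV, ejection
#' fraction, mass change); the pre-ischemia stroke volume is reported as
#' measured (36 ml) rather than as the difference of the rounded volume
#' means (35 ml).
#'
#' @return data.frame with columns `measure`, `unit`, `pre`, `post`.
#' @export
reference_hemodynamics <- function() {
  data.frame(
    measure = c(
      "heart_rate", "lv_mass", "edv", "esv", "sv", "ef", "co"
    ),
    unit = c("bpm", "ml", "ml", "ml", "ml", "%", "l/min"),
    pre = c(81, 86, 82, 47, 36, 44, 2.8),
    post = c(113, 94, 71, 48, 23, 32, 2.6)
  )
}
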