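#' Bundled industrial lye-treatment trial records
#'
#' Reference benchmark tables recorded during industrial cooks of Manzanilla
#' olives: per-method completion-time estimates, the expert-decided real end
#' times, and the corresponding signed relative errors.
#'
#' `"lab"` is a single instrumented laboratory cook followed to completion
#' (real end 8 h at 84.3% treated), tabulated as the prediction evolves from
#' 4 to 8 hourly samples. `"factory"` holds twelve production-tank cooks from
#' two factories, with the prediction made from the last available sampling
#' round of each tank.
#'
#' Columns: `n_samples`, `t_linear`, `t_pchip`, `t_makima` (estimated
#' completion times, hours, 2 d.p.), `t_real` (hours), and recorded signed
#' relative errors `e_linear`, `e_pchip`, `e_makima` (percent); the factory
#' table additionally has `date` and `tank`.
#'
#' @param which `"lab"` or `"factory"`.
#' @return A `data.frame`.
#' @export
olive_trials <- function(which = c("lab", "factory")) {
  which <- match.arg(which)
  file <- c(lab = "lab_trial.csv", factory = "factory_trials.csv")[[which]]
  path <- system.file("extdata", file, package = "olivecook", mustWork = TRUE)
  utils::read.csv(path)
}
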