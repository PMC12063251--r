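#' Bundled example: HbA1c versus FPG point-of-care diabetes screening
#'
#' Path to the bundled configuration (or its ingredient cost table) for the
#' worked example: a societal-perspective comparison of point-of-care HbA1c
#' and fasting plasma glucose screening for type 2 diabetes in a Ugandan
#' outpatient cohort of 1659 adults (diabetes prevalence 8.4\%). The FPG
#' strategy requires a return visit in a fasted state, which doubles the
#' patient's transport exposure and raises meal and lost-productivity costs.
#'
#' @param file `"config"` for the YAML model configuration or
#'   `"ingredients"` for the ingredient cost CSV.
#' @return Path to the installed file.
#' @export
#' @examples
#' cfg <- load_config(example_path("config"))
#' model <- config_to_model(cfg)$model
#' evaluate_cea(model)
example_path <- function(file = c("config", "ingredients")) {
  file <- match.arg(file)
  fn <- switch(file, config = "iganga_2019.yaml",
               ingredients = "iganga_2019_costs.csv")
  system.file("extdata", fn, package = "screencea", mustWork = TRUE)
}
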