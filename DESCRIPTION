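Package: pcmpr
Title: Physiology-Based Climate-Driven Population Dynamics of Aedes albopictus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the seasonal population dynamics of the Asian tiger
    mosquito (Aedes albopictus) in temperate climates from daily weather.  A
    five-stage ordinary-differential-equation model (eggs, diapausing eggs,
    larvae, pupae, adult females) is driven by photoperiod-and-temperature
    controlled egg diapause and by a rainfall-responsive larval carrying
    capacity derived from a soil water balance.  Includes astronomical
    daylength computation, container water-temperature and Thornthwaite
    evapotranspiration sub-models, Poisson-likelihood simulated-annealing
    calibration against weekly trap counts, climate-scenario comparison
    summaries, and a seeded synthetic weather and trap-count generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
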