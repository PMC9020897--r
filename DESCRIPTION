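Package: cardiopredict
Title: Cardiovascular Risk Prediction with a Softsign LSTM and the
    R-Lookahead Optimizer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for tabular cardiovascular-disease risk
    prediction. Generates seeded synthetic cohorts with a known logistic
    ground truth and planted data anomalies; cleans records (duplicate
    removal, blood-pressure and anthropometric outlier filters); derives the
    clinical features body-mass index, mean arterial pressure and pulse
    pressure; ranks features by random-forest Gini impurity importance; and
    classifies with a from-scratch long short-term memory network (standard
    tanh or Softsign candidate activation) trained by backpropagation
    through time under a family of gradient optimizers, including Rectified
    Adam wrapped in Lookahead slow/fast weight averaging ("R-Lookahead").
    Evaluation covers accuracy, precision, recall, specificity, F1 and the
    Matthews correlation coefficient. All user-facing functions are data
    frame in, tibble out, with broom-style tidiers and ggplot2 autoplot
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
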