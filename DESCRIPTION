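Package: screenuse
Title: Daily Smartphone Use Parameters and Their Temporal Stability from
    Screen Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw smartphone screen and notification event logs into
    daily use parameters (total and proactive use frequency and duration,
    and three use/nonuse reciprocity statistics: the root mean square of
    successive differences, the Similarity Index, and the Control Index),
    and analyses their temporal stability across multi-week records: the
    fundamental time unit needed to represent a two-month use pattern, and
    the time interval beyond which two use periods behave as independent
    cycles. Includes a synthetic cohort generator that emulates the
    statistical structure of passively sensed screen-event data, scoring
    for a five-item smartphone addiction inventory, and correlation
    analyses between use parameters and addiction scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
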