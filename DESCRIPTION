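Package: p4psim
Title: System Dynamics Simulation of Payment-for-Performance in Primary
    Health Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time stock-and-flow simulation of primary-care facility
    performance under a payment-for-performance (P4P) programme for maternal
    and child health services. Six coupled sectors (population ageing chain,
    antenatal care demand and services, facility drug commodities, facility
    operations, facility funding, and district manager operations) produce two
    incentivised outcome indicators: the percentage of pregnant women
    receiving at least two doses of intermittent preventive treatment for
    malaria during antenatal care (IPT2), and the percentage of deliveries
    occurring at the facility (FBD). The intervention layer implements
    six-month performance cycles with relative-improvement or absolute
    targets, delayed versus on-time payment calendars, and the
    staff:operations split of bonus payments. Includes a scenario engine,
    one-at-a-time sensitivity analysis with a three-level classification
    scale, extreme-condition validation checks, and a synthetic two-arm
    three-wave evaluation-data generator with a calibration and
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
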