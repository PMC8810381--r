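Package: bristlewing
Title: Flight Mechanics of Bristled-Wing Microinsects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing flapping flight of sub-millimetre insects
    with bristled (feather-like) wings. Builds wing and elytron mass
    properties (mass, centre of mass, inertia tensor) from composite
    geometry of membrane patches and setal rods; reconstructs kinematic
    observables from Euler-angle time series (stroke-plane fit, wingbeat
    cycle detection, phase averaging, angle of attack, Reynolds number,
    clap distance); decomposes aerodynamic forces into lift and drag and
    accounts for vertical force by body part; computes aerodynamic,
    inertial and total mechanical power with elastic-storage scenarios;
    and simulates single-axis body-pitch dynamics with and without the
    inertial braking recoil of the elytra. A seed-deterministic synthetic
    data generator emulates the figure-of-eight wingbeat of miniature
    featherwing beetles so that every stage can be tested without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
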