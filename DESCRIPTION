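Package: stratinvite
Title: Dynamic Stratified-Sampling Invitation Planning for Trial Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans trial invitations by dynamic stratified sampling. For each
    recruitment wave at a site, a linear programme decides how many people to
    invite from each cluster (e.g. general practice) and demographic group so
    that appointment slots fill, under-represented groups are tilted toward,
    and a minimum expected primary-event rate among bookings is achieved,
    mitigating healthy-volunteer effects. Includes a binomial-logistic uptake
    model refitted from between-wave booking feedback, deprivation-stratified
    event-rate mixing, CSV/TXT input-output formats, a closed-loop campaign
    simulator with a synthetic-site generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: boot, stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
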