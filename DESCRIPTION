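Package: microtopics
Title: Topic Modeling of Microbiome Count Data for Community-Type Discovery
Version: 0.1.0
Authors@R: person("Rae", "Whitfield", email = "rw@example.org", role = c("aut", "cre"))
Description: Infers latent bacterial community types from genus-level
    16S count tables with latent Dirichlet allocation fitted by
    variational EM, selects the number of topics with the CaoJuan2009
    and Arun2010 metrics, assigns reads to topics, validates community
    types across cohorts by cosine similarity of topic-term
    distributions, and tests topics and genera for differential
    abundance between two groups with a compositional-bias-corrected
    linear model. Includes a Dirichlet-multinomial cohort simulator for
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    jsonlite,
    withr
Config/testthat/edition: 3
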