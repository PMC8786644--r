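# small in-code fixtures shared across test files

tiny_expression <- function() {
  m <- matrix(0:5, nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("gA", "gB", "gC")))
  storage.mode(m) <- "double"
  m
}

write_tiny_expression_tsv <- function(path) {
  writeLines(c("patient_id\tgA\tgB\tgC",
               "p1\t0\t1\t2",
               "p2\t3\t4\t5"), path)
  path
}

tiny_clinical_tsv <- function(path) {
  writeLines(c("patient_id\tcohort\tage\tgender\tevent\ttime",
               "p1\tBRCA\t61\tfemale\t1\t455",
               "p2\tBRCA\t\tmale\t0\t1000",      # missing age
               "p3\tBRCA\t58\tfemale\t1\t0",     # nonpositive time
               "p4\tLUAD\t70\tmale\t0\t320",
               "p5\tLUAD\t49\tfemale\t1\t90"), path)
  path
}

# quick single-cohort survival data without the generator, for Cox tests
random_survival <- function(n, seed = 1L, frac_event = 0.6) {
  set.seed(seed)
  list(scores = rnorm(n),
       time = rexp(n, 0.01) + 1e-3,
       event = rbinom(n, 1, frac_event))
}
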