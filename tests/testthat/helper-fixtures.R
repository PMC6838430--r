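# Shared fixtures: the ten published repeat structures (representative q1
# where the table leaves it symbolic) and a small random-structure factory.

table1_structures <- function() {
  list(
    typical        = allele_structure(43, caacag = 1, ccgcca = 1, p2 = 7, p3 = 2),
    duplication    = allele_structure(40, caacag = 2, ccgcca = 1, p2 = 7, p3 = 3),
    s17_2_0_6_2    = allele_structure(17, caacag = 1, ccgcca = 0, p2 = 6, p3 = 2),
    s_2_0_9_2      = allele_structure(20, caacag = 1, ccgcca = 0, p2 = 9, p3 = 2),
    s_2_2_9_3      = allele_structure(22, caacag = 1, ccgcca = 1, p2 = 9, p3 = 3),
    del_2_7_2      = allele_structure(42, caacag = 0, ccgcca = 1, p2 = 7, p3 = 2),
    s20_0_2_11_2   = allele_structure(20, caacag = 0, ccgcca = 1, p2 = 11, p3 = 2),
    s41_0_0_9_2    = allele_structure(41, caacag = 0, ccgcca = 0, p2 = 9, p3 = 2),
    s_0_0_11_2     = allele_structure(44, caacag = 0, ccgcca = 0, p2 = 11, p3 = 2),
    caa_interrupt  = allele_structure(41, extra_caa = 1, caacag = 1,
                                      ccgcca = 1, p2 = 7, p3 = 2))
}

random_structure <- function() {
  allele_structure(q1 = sample(1:60, 1),
                   extra_caa = sample(0:1, 1),
                   caacag = sample(0:3, 1),
                   ccgcca = sample(0:2, 1),
                   p2 = sample(0:12, 1),
                   p3 = sample(0:3, 1))
}

# minimal phenotype frame satisfying the SE-model contract
make_se_cohort <- function(n, seed = 1, beta = c(int = 0.3, age = 0.004,
                                                 q1 = 0.04, inter = 0.001),
                           noise_sd = 0.03) {
  set.seed(seed)
  d <- data.frame(
    age = runif(n, 20, 70),
    q1 = sample(40:50, n, replace = TRUE),
    q2 = sample(c(2, 2, 2, 2, 0, 4), n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    cohort = sample(c("A", "B"), n, replace = TRUE))
  d$qt <- d$q1 + d$q2
  ac <- d$age - mean(d$age)
  qc <- d$q1 - mean(d$q1)
  d$expansion_ratio <- beta[["int"]] + beta[["age"]] * ac +
    beta[["q1"]] * qc + beta[["inter"]] * ac * qc +
    rnorm(n, 0, noise_sd)
  d
}
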