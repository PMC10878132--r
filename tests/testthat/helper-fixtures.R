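# Shared fixtures: a minimal hand-written study row and small generator
# configurations used across test files.

make_study <- function(study_id = "S1", matrix = "urine",
                       province = "Guangdong", year_start = 2010L,
                       year_end = 2010L, sex = "mixed", age_min = 19L,
                       age_max = 44L, n = 50L, summary_kind = "GM_GSD",
                       s1 = 2, s2 = 2, s3 = NA_real_, unit = "ng/mL",
                       lod = 1) {
  data.frame(study_id = study_id, matrix = matrix, province = province,
             year_start = year_start, year_end = year_end, sex = sex,
             age_min = age_min, age_max = age_max, n = n,
             summary_kind = summary_kind, s1 = s1, s2 = s2, s3 = s3,
             unit = unit, lod = lod, stringsAsFactors = FALSE)
}

tiny_temporal_config <- function(seed = 3) {
  generator_config(studies_per_stratum = 4, n_range = c(20, 80),
                   seed = seed)
}

tiny_province_config <- function(seed = 9, n_provinces = 18) {
  generator_config(strata = province_truth(n_provinces = n_provinces),
                   studies_per_stratum = 3, n_range = c(20, 60),
                   seed = seed)
}
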