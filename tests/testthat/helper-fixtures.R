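# 20-person hand-built episode fixture exercising every ascertainment rule.
fixture_episodes <- function() {
  ep <- function(p, sys, code, date) {
    data.frame(person_id = p, system = sys, code = code, date = date,
               stringsAsFactors = FALSE)
  }
  rbind(
    ep("P01", "ICD10", "E11.3", "2010-01-01"), ep("P01", "ICD10", "I21.0", "2010-01-02"),
    ep("P02", "ICD10", "E11.0", "2010-01-01"), ep("P02", "ICD10", "I63.9", "2010-01-01"),
    ep("P03", "ICD10", "E11.9", "2015-06-01"),
    ep("P04", "ICD10", "E11.1", "2000-03-15"), ep("P04", "ICD10", "I50.0", "2005-07-20"),
    ep("P05", "ICD10", "E11.5", "2010-05-05"), ep("P05", "ICD10", "I21.9", "2021-03-01"),
    ep("P06", "ICD10", "E11.2", "2012-02-29"),
    ep("P07", "ICD10", "E11.4", "2010-01-10"), ep("P07", "ICD10", "I22.1", "2009-12-31"),
    ep("P08", "ICD10", "E11.6", "2018-11-01"), ep("P08", "ICD10", "I63.0", "2018-11-20"),
    ep("P09", "ICD10", "E11.8", "2019-01-01"), ep("P09", "ICD10", "I50.9", "2019-02-15"),
    ep("P10", "ICD10", "E11.7", "2005-09-09"), ep("P10", "OPCS4", "K40.2", "2007-01-01"),
    ep("P11", "ICD10", "I21.4", "2012-12-12"),
    ep("P12", "ICD10", "E11.9", "2010-06-01"),
    ep("P13", "ICD9", "250.0", "2010-01-01"), ep("P13", "ICD9", "410.9", "2012-01-01"),
    ep("P14", "ICD10", "E11.9", "2010-01-01"),
    ep("P15", "ICD10", "E11.9", "2010-01-01"), ep("P15", "ICD10", "I25.1", "2014-05-05"),
    ep("P15", "ICD10", "I21.2", "2012-03-03"),
    ep("P16", "ICD10", "E11.9", "2016-08-08"), ep("P16", "ICD10", "I63.3", "2016-08-09"),
    ep("P16", "ICD10", "I50.1", "2016-08-10"),
    ep("P17", "ICD10", "E11.9", "2010-10-10"), ep("P17", "ICD10", "J45.9", "2011-01-01"),
    ep("P18", "ICD10", "E11.9", "2013-03-03"), ep("P18", "ICD10", "I21.8", "2013-04-04"),
    ep("P19", "ICD10", "E11.9", "2020-12-31"),
    ep("P20", "ICD10", "E11.9", "2010-01-01"), ep("P20", "ICD10", "I21.3", "2009-01-01"),
    ep("P20", "ICD10", "I63.2", "2015-01-01")
  )
}

fixture_deaths <- function() {
  data.frame(person_id = c("P03", "P12", "P14", "P18"),
             date = c("2018-06-01", "2010-06-25", "2020-06-30", "2014-01-01"),
             stringsAsFactors = FALSE)
}

# Hand-derived truth: event status and follow-up end date per retained person.
fixture_expected <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
person_id t2d        end        event
P01       2010-01-01 2010-01-02 1
P03       2015-06-01 2018-06-01 0
P04       2000-03-15 2005-07-20 1
P05       2010-05-05 2021-02-05 0
P06       2012-02-29 2021-02-05 0
P08       2018-11-01 2018-11-20 1
P09       2019-01-01 2019-02-15 1
P10       2005-09-09 2007-01-01 1
P12       2010-06-01 2010-06-25 0
P13       2010-01-01 2012-01-01 1
P14       2010-01-01 2020-06-30 0
P15       2010-01-01 2012-03-03 1
P16       2016-08-08 2016-08-09 1
P17       2010-10-10 2021-02-05 0
P18       2013-03-03 2013-04-04 1
P19       2020-12-31 2021-02-05 0")
  tab$follow_up_days <- as.numeric(as.Date(tab$end) - as.Date(tab$t2d))
  tab
}

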