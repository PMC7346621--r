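{
  "language": "de",
  "matching": {"mode": "word_boundary", "case_sensitive": false},
  "entries": [
    {
      "factor_id": "meal_dependent",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["Mahlzeit", "Essen", "essen", "Frühstück", "Mittagessen", "Abendessen", "nüchtern"]
    },
    {
      "factor_id": "once_weekly",
      "provenance": "repo-default",
      "fields": ["instructions", "scheme_text"],
      "phrases": ["einmal wöchentlich", "1x wöchentlich", "wöchentlich", "einmal pro Woche", "jede Woche"]
    },
    {
      "factor_id": "every_two_days_or_less",
      "provenance": "repo-default",
      "fields": ["instructions", "scheme_text"],
      "phrases": ["alle zwei Tage", "jeden zweiten Tag", "alle drei Tage", "einmal monatlich", "jeden Monat"]
    },
    {
      "factor_id": "fixed_dosing_interval",
      "provenance": "repo-default",
      "fields": ["instructions", "scheme_text"],
      "phrases": ["alle 6 Stunden", "alle 8 Stunden", "alle 12 Stunden", "fester Abstand", "gleichmäßiger Abstand"]
    },
    {
      "factor_id": "occasional_episodic",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["kurzzeitig", "zeitlich begrenzt", "bis Packung aufgebraucht", "nur eine Woche"]
    },
    {
      "factor_id": "prn_medication",
      "provenance": "repo-default",
      "fields": ["instructions", "scheme_text"],
      "phrases": ["bei Bedarf", "nach Bedarf", "falls erforderlich", "wenn nötig"]
    },
    {
      "factor_id": "crushing_tablets",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["zerkleinern", "zerkleinert", "mörsern", "gemörsert"]
    },
    {
      "factor_id": "disintegrating_forms",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["auflösen", "aufgelöst", "Brausetablette", "dispergieren"]
    },
    {
      "factor_id": "fixed_times_of_day",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["zur Nacht", "feste Uhrzeit", "um 8 Uhr", "um 20 Uhr", "bestimmte Uhrzeit"]
    },
    {
      "factor_id": "advised_liquid_intake",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["viel Wasser", "Glas Wasser", "mit Milch", "mit Saft", "aufrecht einnehmen"]
    },
    {
      "factor_id": "opening_capsules",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["Kapsel öffnen", "Kapseln öffnen", "Inhalt ausstreuen", "Kapsel darf geöffnet werden"]
    },
    {
      "factor_id": "increasing_doses",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["Dosis steigern", "aufdosieren", "Aufdosierung", "Dosissteigerung", "einschleichen"]
    },
    {
      "factor_id": "decreasing_doses",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["Dosis reduzieren", "abdosieren", "Abdosierung", "ausschleichen", "Dosisreduktion"]
    },
    {
      "factor_id": "complex_measurements",
      "provenance": "repo-default",
      "fields": ["instructions"],
      "phrases": ["Blutzucker", "Gerinnung", "INR", "Selbstmessung", "nach Messwert"]
    }
  ]
}
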