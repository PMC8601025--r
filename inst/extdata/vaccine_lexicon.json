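{
  "version": "1.0.0",
  "filter_terms": {
    "covid": ["covid", "coronavirus", "corona"],
    "vaccine": ["vaccine", "vaccination", "vaccinated", "vax"]
  },
  "categories": {
    "availability": [
      "alabama", "alaska", "arizona", "arkansas", "california", "colorado",
      "connecticut", "delaware", "florida", "georgia", "hawaii", "idaho",
      "illinois", "indiana", "iowa", "kansas", "kentucky", "louisiana",
      "maine", "maryland", "massachusetts", "michigan", "minnesota",
      "mississippi", "missouri", "montana", "nebraska", "nevada",
      "new hampshire", "new jersey", "new mexico", "new york",
      "north carolina", "north dakota", "ohio", "oklahoma", "oregon",
      "pennsylvania", "rhode island", "south carolina", "south dakota",
      "tennessee", "texas", "utah", "vermont", "virginia", "washington",
      "west virginia", "wisconsin", "wyoming",
      "ny", "nyc", "nj", "tx", "fl", "pa", "az", "ga",
      "near me", "where", "when", "appointment", "pharmacy", "hospital",
      "clinic", "site", "location", "county", "sign up", "register",
      "registration", "finder",
      "cvs", "walgreens", "rite aid", "walmart", "kroger", "costco",
      "safeway", "publix", "meijer", "sam's club"
    ],
    "manufacturer": [
      "pfizer", "moderna", "johnson", "j&j", "janssen", "astrazeneca",
      "astra zeneca", "biontech", "novavax"
    ],
    "side_effects_safety": [
      "side effects", "safety", "safe", "reaction", "blood clot", "clot",
      "fever", "allergy", "allergic", "pregnant", "pregnancy", "headache",
      "sore arm", "chills", "fatigue", "nausea", "rash", "myocarditis",
      "problems", "worries", "worried", "concerns", "dangerous", "danger",
      "risks", "risk", "death"
    ],
    "myths_conspiracy": [
      "infertility", "fertility", "infertile", "dna", "microchip", "5g",
      "covid from vaccine", "covid from the vaccine", "magnetic", "magnet",
      "conspiracy", "hoax", "bill gates"
    ]
  },
  "pharmacy_names": [
    "cvs", "walgreens", "rite aid", "walmart", "kroger", "costco",
    "safeway", "publix", "meijer", "sam's club"
  ],
  "variants": {
    "vaccines": "vaccine",
    "vaccinations": "vaccine",
    "vacine": "vaccine",
    "vacines": "vaccine",
    "vaccin": "vaccine",
    "vacination": "vaccination",
    "vaccinate": "vaccinated",
    "vaxx": "vax",
    "phizer": "pfizer",
    "pfiser": "pfizer",
    "pfizers": "pfizer",
    "fizer": "pfizer",
    "maderna": "moderna",
    "modernas": "moderna",
    "jansen": "janssen",
    "jannsen": "janssen",
    "johnsons": "johnson",
    "astrazenica": "astrazeneca",
    "astrazenca": "astrazeneca",
    "effect": "effects",
    "affects": "effects",
    "affect": "effects",
    "reactions": "reaction",
    "allergies": "allergy",
    "clots": "clot",
    "fevers": "fever",
    "appointments": "appointment",
    "appt": "appointment",
    "appts": "appointment",
    "walgreen": "walgreens",
    "walmarts": "walmart",
    "microchips": "microchip",
    "pharmacies": "pharmacy",
    "hospitals": "hospital",
    "clinics": "clinic",
    "sites": "site",
    "locations": "location",
    "counties": "county"
  },
  "general_patterns": [
    "covid vaccine",
    "covid 19 vaccine",
    "coronavirus vaccine",
    "corona vaccine",
    "covid vaccination",
    "covid 19 vaccination",
    "the covid vaccine",
    "covid vax"
  ]
}
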